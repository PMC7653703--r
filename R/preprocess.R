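#' Normalize a log2-ratio profile
#'
#' Median- (default) or mode-centers a profile so the bulk of the genome
#' sits at log2 ratio 0.  Relative differences between probes are
#' preserved exactly.
#'
#' @param x numeric vector of log2 ratios (one sample).
#' @param method `"median"` (default) or `"mode"` (highest kernel
#'   density peak).
#' @return the centered profile.
#' @export
normalize_profile <- function(x, method = c("median", "mode")) {
  method <- match.arg(method)
  if (all(is.na(x))) stop("profile contains no values")
  if (any(!is.finite(x[!is.na(x)]))) stop("profile values must be finite")
  center <- if (method == "median") median(x, na.rm = TRUE) else {
    d <- density(x[!is.na(x)])
    d$x[which.max(d$y)]
  }
  x - center
}

#' Normalize every row of a samples-by-probes matrix
#' @param l2r numeric matrix, samples x probes.
#' @inheritParams normalize_profile
#' @export
normalize_profiles <- function(l2r, method = "median") {
  t(apply(l2r, 1, normalize_profile, method = method))
}

#' Derivative log ratio spread (DLRS)
#'
#' Robust per-sample noise estimate: the interquartile range of lag-1
#' probe-to-probe differences, taken within chromosomes only (so
#' segment steps at chromosome boundaries never contribute), divided by
#' the Gaussian-consistency constant `1.349 * sqrt(2)`.  For pure
#' Gaussian noise of standard deviation `s` the DLRS converges to `s`.
#'
#' @param x numeric log2-ratio vector aligned to `probe_map`.
#' @param probe_map probe map ordering the values genomically.
#' @return the DLRS (a non-negative scalar, log2 units).
#' @export
compute_dlrs <- function(x, probe_map) {
  stopifnot_probe_map(probe_map)
  if (length(x) != nrow(probe_map))
    stop("profile length must equal the probe map length")
  d <- unlist(lapply(split(x, probe_map$chrom), diff), use.names = FALSE)
  if (length(d) < 2L)
    stop("insufficient data: need >= 3 probes contributing differences")
  IQR(d, na.rm = TRUE) / (1.349 * sqrt(2))
}

#' Per-sample quality-control metrics
#'
#' @param l2r samples x probes matrix.
#' @param probe_map probe map.
#' @param dlrs_exclude exclusion threshold (samples with DLRS strictly
#'   above are failed).
#' @param dlrs_loh LOH-eligibility threshold (strictly below).
#' @return data.frame `sample_id`, `dlrs`, `pass`, `loh_eligible`.
#' @export
qc_metrics <- function(l2r, probe_map, dlrs_exclude = 0.47,
                       dlrs_loh = 0.3) {
  dlrs <- apply(l2r, 1, compute_dlrs, probe_map = probe_map)
  data.frame(sample_id = rownames(l2r), dlrs = dlrs,
             pass = dlrs <= dlrs_exclude,
             loh_eligible = dlrs < dlrs_loh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition samples by DLRS quality control
#'
#' A sample is excluded iff its DLRS is strictly greater than the
#' threshold (a DLRS exactly at the threshold is kept).
#'
#' @param metrics data.frame from [qc_metrics()].
#' @param threshold exclusion threshold (default 0.47).
#' @return list with `kept` and `excluded` data.frames; `excluded`
#'   carries a `reason` column.
#' @export
apply_qc <- function(metrics, threshold = 0.47) {
  excl <- metrics$dlrs > threshold
  excluded <- metrics[excl, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("DLRS %.3f > %.2f", excluded$dlrs, threshold)
  else excluded$reason <- character(0)
  list(kept = metrics[!excl, , drop = FALSE], excluded = excluded)
}

## Group segment mean levels by probe-weighted 1-D clustering: sorted
## means are split where consecutive gaps exceed `tol`; each level's
## value is its probe-weighted mean.
segment_levels <- function(segments, tol = 0.1) {
  o <- order(segments$mean_l2r)
  m <- segments$mean_l2r[o]
  w <- segments$n_probes[o]
  grp <- cumsum(c(1, diff(m) > tol))
  data.frame(level = as.numeric(tapply(m * w, grp, sum) /
                                  tapply(w, grp, sum)),
             weight = as.numeric(tapply(w, grp, sum)))
}

#' Centralize a segmented profile
#'
#' Shifts a profile so that its inferred copy-neutral level sits at
#' log2 ratio 0.  The shift is only applied when the profile carries at
#' least one candidate alteration (a segment with |mean| beyond the
#' state thresholds) spanning at least `min_span` base pairs; otherwise
#' the profile is returned unchanged with offset 0.  The copy-neutral
#' level is taken as the probe-weight-dominant segment-mean level
#' ("largest-span level = neutral"), a data-driven surrogate for
#' anchoring the neutral state externally (e.g. by FISH).  The offset is
#' a pure shift and is returned so callers can audit or override it.
#'
#' @param x numeric log2-ratio vector.
#' @param segments segmentation of `x` (see [cbs_segment()]).
#' @param min_span minimum alteration span triggering centralization
#'   (base pairs, default 5 Mb).
#' @param gain_thr,loss_thr state thresholds defining a candidate
#'   alteration (log2 units).
#' @param level_tol gap (log2 units) separating distinct mean levels.
#' @return list with `profile` (shifted values), `offset` (log2 units),
#'   and `segments` (input segmentation with means shifted identically).
#' @export
centralize_profile <- function(x, segments, min_span = 5e6,
                               gain_thr = 0.25, loss_thr = -0.25,
                               level_tol = 0.1) {
  if (is.null(segments) || nrow(segments) == 0L)
    stop("missing segmentation: centralization needs segments")
  span <- segments$end_pos - segments$start_pos + 1
  candidate <- (segments$mean_l2r >= gain_thr |
                  segments$mean_l2r <= loss_thr) & span >= min_span
  if (!any(candidate))
    return(list(profile = x, offset = 0, segments = segments))
  lev <- segment_levels(segments, tol = level_tol)
  neutral <- lev$level[which.max(lev$weight)]
  offset <- -neutral
  seg2 <- segments
  seg2$mean_l2r <- seg2$mean_l2r + offset
  list(profile = x + offset, offset = offset, segments = seg2)
}
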