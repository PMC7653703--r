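#' Segmentation configuration
#'
#' @param alpha change-point acceptance level (default 1e-6).
#' @param n_perm permutations per change-point test.  Raw permutation
#'   cannot certify p-values below `1/(n_perm + 1)`; levels as small as
#'   1e-6 become operational through the Gaussian tail approximation
#'   (see `use_approx`).
#' @param gain_thr,loss_thr segment-state thresholds (log2 units);
#'   a segment is called gained iff its mean is `>= gain_thr`, lost iff
#'   `<= loss_thr`, both boundaries inclusive.
#' @param min_probes minimum probes per segment.
#' @param use_approx when the observed statistic exceeds every permuted
#'   maximum, refine the p-value with a Bonferroni-over-arcs Gaussian
#'   tail bound (the approximation that makes `alpha = 1e-6`
#'   reachable).  With `use_approx = FALSE` the permutation p-value is
#'   used as-is and `alpha` below `1/(n_perm + 1)` can never accept.
#' @param seed integer seed for the permutation stream.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(alpha = 1e-6, n_perm = 39L, gain_thr = 0.25,
                       loss_thr = -0.25, min_probes = 3L,
                       use_approx = TRUE, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (gain_thr <= 0 || loss_thr >= 0)
    stop("gain threshold must be > 0 > loss threshold")
  if (min_probes < 1L) stop("min_probes must be >= 1")
  out <- list(alpha = alpha, n_perm = as.integer(n_perm),
              gain_thr = gain_thr, loss_thr = loss_thr,
              min_probes = as.integer(min_probes),
              use_approx = isTRUE(use_approx), seed = as.integer(seed))
  class(out) <- c("seg_config", "list")
  out
}

## Change-point test for one candidate split.  Returns log p-value.
## Hybrid rule: a coarse permutation screen; when the observed maximal
## statistic beats every permuted maximum, a Bonferroni Gaussian tail
## bound (on the log scale, so levels far below double-precision
## underflow remain comparable).
cbs_test_logp <- function(x, s, min_w, config, seed) {
  res <- cbs_max_arc(x, s, min_w)
  if (res$stat <= 0) return(list(logp = 0, res = res))
  perm <- cbs_perm_exceed(x, s, min_w, res$stat, config$n_perm, seed,
                          config$alpha)
  if (perm$n_ge > 0L || !config$use_approx) {
    p <- (1 + perm$n_ge) / (perm$n_done + 1)
    return(list(logp = log(p), res = res))
  }
  logp <- log(res$n_arcs) + log(2) + pnorm(res$stat, lower.tail = FALSE,
                                           log.p = TRUE)
  list(logp = min(logp, 0), res = res)
}

## Recursive binary segmentation of one chromosome (local indices).
cbs_one_chrom <- function(x, config, s, seed_base) {
  n <- length(x)
  min_w <- config$min_probes
  bounds <- integer(0)              # accepted internal change-points
  counter <- 0L
  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_w) return(invisible(NULL))
    counter <<- counter + 1L
    tst <- cbs_test_logp(x[lo:hi], s, min_w, config,
                         seed = seed_base + counter)
    if (tst$logp >= log(config$alpha)) return(invisible(NULL))
    i <- tst$res$i; j <- tst$res$j   # local arc (i, j]
    cuts <- integer(0)
    if (i > 0L) cuts <- c(cuts, lo + i - 1L)
    if (j < m) cuts <- c(cuts, lo + j - 1L)
    if (!length(cuts)) return(invisible(NULL))
    bounds <<- c(bounds, cuts)
    starts <- c(lo, cuts + 1L)
    ends <- c(cuts, hi)
    for (p in seq_along(starts)) recurse(starts[p], ends[p])
    invisible(NULL)
  }
  recurse(1L, n)
  sort(unique(bounds))
}

#' Circular binary segmentation of a log2-ratio profile
#'
#' Per chromosome, recursively finds the circular arc maximizing the
#' standardized two-sample statistic comparing probes inside vs outside
#' the arc, and accepts its change-points iff the hybrid permutation /
#' Gaussian-tail p-value is below `alpha` (see [seg_config()]).  The
#' per-chromosome noise scale is estimated robustly from lag-1 probe
#' differences (`mad(diff(x)) / sqrt(2)`).  Chromosomes with fewer than
#' `2 * min_probes` probes are returned as a single untested segment.
#' Output segments tile every chromosome: contiguous, non-overlapping,
#' covering all probes.  Coordinates are 1-based and inclusive.
#'
#' @param x numeric log2-ratio vector aligned to `probe_map`
#'   (normalized, and centralized if required).
#' @param probe_map probe map.
#' @param config a [seg_config()].
#' @return data.frame with columns `chrom`, `start_idx`, `end_idx`
#'   (global probe indices), `start_pos`, `end_pos`, `n_probes`,
#'   `mean_l2r`.
#' @export
cbs_segment <- function(x, probe_map, config = seg_config()) {
  stopifnot_probe_map(probe_map)
  if (length(x) != nrow(probe_map))
    stop("profile length must equal the probe map length")
  idx_by_chr <- split(seq_along(x), probe_map$chrom)
  out <- vector("list", length(idx_by_chr))
  for (ci in seq_along(idx_by_chr)) {
    idx <- idx_by_chr[[ci]]
    xs <- x[idx]
    n <- length(xs)
    if (n >= 2L * config$min_probes && n >= 3L) {
      s <- max(mad(diff(xs)) / sqrt(2), 1e-10)
      bnds <- cbs_one_chrom(xs, config, s,
                            seed_base = config$seed * 10000L + ci * 100L)
    } else bnds <- integer(0)
    starts <- c(1L, bnds + 1L)
    ends <- c(bnds, n)
    out[[ci]] <- data.frame(
      chrom = probe_map$chrom[idx[1]],
      start_idx = idx[starts], end_idx = idx[ends],
      start_pos = probe_map$pos[idx[starts]],
      end_pos = probe_map$pos[idx[ends]],
      n_probes = ends - starts + 1L,
      mean_l2r = vapply(seq_along(starts), function(k)
        mean(xs[starts[k]:ends[k]]), numeric(1)))
  }
  do.call(rbind, out)
}

#' Call gain / neutral / loss states on segments
#'
#' State = gain iff the segment mean is `>= gain_thr`, loss iff
#' `<= loss_thr` (both inclusive), neutral otherwise.
#'
#' @param segments segment table from [cbs_segment()].
#' @param config a [seg_config()] carrying the thresholds.
#' @return the segment table with a `state` column
#'   (`"gain"`/`"neutral"`/`"loss"`).
#' @export
call_segment_states <- function(segments, config = seg_config()) {
  if (any(!is.finite(segments$mean_l2r)))
    stop("segment means must be finite")
  segments$state <- ifelse(segments$mean_l2r >= config$gain_thr, "gain",
                    ifelse(segments$mean_l2r <= config$loss_thr, "loss",
                           "neutral"))
  segments
}

#' Build the cohort alteration matrix
#'
#' Every probe inherits the state of its covering segment:
#' -1 (deleted), 0 (normal), +1 (gained).
#'
#' @param segment_sets named list (by sample id) of state-called
#'   segment tables.
#' @param probe_map probe map.
#' @return integer matrix, samples x probes.
#' @export
build_alteration_matrix <- function(segment_sets, probe_map) {
  stopifnot_probe_map(probe_map)
  n_probes <- nrow(probe_map)
  code <- c(gain = 1L, neutral = 0L, loss = -1L)
  out <- matrix(0L, length(segment_sets), n_probes,
                dimnames = list(names(segment_sets), probe_map$probe_id))
  for (i in seq_along(segment_sets)) {
    seg <- segment_sets[[i]]
    if (is.null(seg$state)) stop("segments must carry called states")
    covered <- sum(seg$n_probes)
    if (covered != n_probes)
      stop("internal consistency error: segments cover ", covered,
           " of ", n_probes, " probes for sample ",
           names(segment_sets)[i])
    for (r in seq_len(nrow(seg)))
      out[i, seg$start_idx[r]:seg$end_idx[r]] <- code[[seg$state[r]]]
  }
  out
}
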