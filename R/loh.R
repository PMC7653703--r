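#' Call copy-neutral LOH from SNP-probe homozygosity runs
#'
#' Surrogate for vendor LOH callers: maximal runs of consecutive
#' homozygous SNP probes, restricted to copy-neutral probes (runs are
#' broken by any gained or deleted probe, since a deletion already
#' explains the homozygosity), that meet both a minimum SNP count and a
#' minimum genomic span.  Samples whose DLRS is not strictly below the
#' eligibility threshold are not assessed and return an empty table
#' flagged accordingly.
#'
#' @param homozygous logical vector over the sample's SNP probes (TRUE
#'   = homozygous call), aligned with the SNP rows of `probe_map`.
#' @param alteration_row integer vector over all probes (-1/0/+1) for
#'   the same sample.
#' @param probe_map probe map (its `class == "SNP"` rows align with
#'   `homozygous`).
#' @param dlrs the sample's DLRS.
#' @param min_snps minimum SNPs per reported run.
#' @param min_span minimum run span in base pairs.
#' @param dlrs_loh eligibility threshold (default 0.3, strict).
#' @return data.frame of intervals (`chrom`, `start`, `end`, `n_snps`)
#'   with attribute `assessed` (FALSE when the DLRS gate failed or no
#'   SNP probes exist).
#' @export
call_cnloh <- function(homozygous, alteration_row, probe_map, dlrs,
                       min_snps = 25L, min_span = 10e6,
                       dlrs_loh = 0.3) {
  stopifnot_probe_map(probe_map)
  empty <- data.frame(chrom = integer(), start = numeric(),
                      end = numeric(), n_snps = integer())
  snp_idx <- which(probe_map$class == "SNP")
  if (!length(snp_idx)) {
    attr(empty, "assessed") <- FALSE
    return(empty)
  }
  if (length(homozygous) != length(snp_idx))
    stop("'homozygous' must align with the probe map's SNP probes")
  if (!is.na(dlrs) && dlrs >= dlrs_loh) {
    attr(empty, "assessed") <- FALSE
    return(empty)
  }
  neutral <- alteration_row[snp_idx] == 0L
  eligible <- homozygous & neutral
  chrom <- probe_map$chrom[snp_idx]
  pos <- probe_map$pos[snp_idx]

  out <- list()
  for (ci in unique(chrom)) {
    sel <- chrom == ci
    r <- rle(eligible[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    p <- pos[sel]
    for (k in which(r$values)) {
      n_run <- r$lengths[k]
      span <- p[ends[k]] - p[starts[k]]
      if (n_run >= min_snps && span >= min_span)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ci, start = p[starts[k]], end = p[ends[k]],
          n_snps = n_run)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "assessed") <- TRUE
  res
}

#' Build the cohort cnLOH probe matrix
#'
#' @param loh_calls named list (by sample) of interval tables from
#'   [call_cnloh()].
#' @param probe_map probe map.
#' @return logical matrix samples x probes, TRUE where a probe lies in
#'   a called cnLOH interval.
#' @export
build_loh_matrix <- function(loh_calls, probe_map) {
  stopifnot_probe_map(probe_map)
  out <- matrix(FALSE, length(loh_calls), nrow(probe_map),
                dimnames = list(names(loh_calls), probe_map$probe_id))
  for (i in seq_along(loh_calls)) {
    iv <- loh_calls[[i]]
    if (nrow(iv)) for (r in seq_len(nrow(iv)))
      out[i, probe_map$chrom == iv$chrom[r] &
             probe_map$pos >= iv$start[r] &
             probe_map$pos <= iv$end[r]] <- TRUE
  }
  out
}
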