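#' Generate a synthetic aCGH probe map
#'
#' Spreads `n_probes` uniformly across the 22 autosomes proportionally to
#' chromosome length (every chromosome receives at least one probe) and
#' assigns a random subset the SNP class, mimicking a combined CGH+SNP
#' array design.
#'
#' @param genome a [genome_spec()].
#' @param n_probes total number of probes (>= 22).
#' @param snp_fraction proportion of probes carrying the SNP class, in
#'   `[0, 1)`; the remainder are CGH probes.
#' @param seed integer seed; identical seeds give identical maps.
#' @return a `data.frame` with columns `probe_id`, `chrom`, `pos`,
#'   `class` (`"CGH"` or `"SNP"`), sorted by (chrom, pos), of class
#'   `probe_map`.
#' @export
generate_probe_map <- function(genome, n_probes, snp_fraction = 0, seed = 1L) {
  stopifnot_genome(genome)
  n_probes <- as.integer(n_probes)
  if (n_probes < nrow(genome))
    stop("n_probes must be at least the number of chromosomes (22)")
  if (snp_fraction < 0 || snp_fraction >= 1)
    stop("snp_fraction must be in [0, 1)")
  set.seed(as.integer(seed))

  ## one probe per chromosome guaranteed; the rest allocated by length
  ## with largest-remainder rounding
  extra <- n_probes - nrow(genome)
  quota <- extra * genome$length / sum(genome$length)
  n_chr <- floor(quota)
  rem <- extra - sum(n_chr)
  if (rem > 0) {
    take <- order(quota - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[take] <- n_chr[take] + 1
  }
  n_chr <- n_chr + 1L

  pieces <- lapply(seq_len(nrow(genome)), function(ci) {
    k <- n_chr[ci]
    pos <- sort(sample.int(genome$length[ci], k, replace = FALSE))
    data.frame(chrom = rep(genome$chrom[ci], k), pos = pos)
  })
  out <- do.call(rbind, pieces)
  out$probe_id <- sprintf("c%02dp%07d", out$chrom, ave(out$pos, out$chrom,
    FUN = seq_along))
  n_snp <- round(n_probes * snp_fraction)
  out$class <- "CGH"
  if (n_snp > 0)
    out$class[sample.int(n_probes, n_snp)] <- "SNP"
  out <- out[, c("probe_id", "chrom", "pos", "class")]
  rownames(out) <- NULL
  class(out) <- c("probe_map", "data.frame")
  out
}

stopifnot_probe_map <- function(probe_map) {
  need <- c("probe_id", "chrom", "pos", "class")
  if (!is.data.frame(probe_map) || !all(need %in% names(probe_map)))
    stop("'probe_map' must have columns probe_id, chrom, pos, class")
  if (is.unsorted(order(probe_map$chrom, probe_map$pos)))
    stop("'probe_map' must be sorted by (chrom, pos)")
  invisible(probe_map)
}

#' Write / read a probe map as 4-column TSV
#'
#' Columns: `chrom`, `pos`, `probe_id`, `class`.  Positions are 1-based.
#'
#' @param probe_map a probe map.
#' @param path file path.
#' @return `read_probe_map` returns a `probe_map` data.frame.
#' @export
write_probe_map <- function(probe_map, path) {
  stopifnot_probe_map(probe_map)
  data.table::fwrite(probe_map[, c("chrom", "pos", "probe_id", "class")],
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  out <- out[order(out$chrom, out$pos), c("probe_id", "chrom", "pos", "class")]
  rownames(out) <- NULL
  class(out) <- c("probe_map", "data.frame")
  out
}
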