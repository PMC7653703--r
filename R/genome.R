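#' Autosomal genome specification
#'
#' A genome specification holds the 22 autosome lengths and one arm
#' boundary (centromere position) per chromosome.  Sex chromosomes are
#' excluded from every analysis in this package, so they are not
#' representable.
#'
#' @param lengths integer vector of 22 chromosome lengths in base pairs,
#'   ordered chr1..chr22.
#' @param centromeres integer vector of 22 centromere positions, each
#'   strictly inside its chromosome.
#' @return a `data.frame` with columns `chrom` (1..22), `length`,
#'   `centromere`, of class `genome_spec`.
#' @export
genome_spec <- function(lengths, centromeres) {
  if (length(lengths) != 22L || length(centromeres) != 22L)
    stop("a genome specification requires exactly 22 autosomes")
  lengths <- as.numeric(lengths)
  centromeres <- as.numeric(centromeres)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (any(centromeres <= 0) || any(centromeres >= lengths))
    stop("arm boundaries must lie strictly inside their chromosome")
  out <- data.frame(chrom = 1:22, length = lengths, centromere = centromeres)
  class(out) <- c("genome_spec", "data.frame")
  out
}

#' hg19-style autosome lengths and centromere positions
#'
#' Default genome used by the synthetic cohort generator: GRCh37/hg19
#' autosome lengths with approximate centromere midpoints.
#'
#' @return a `genome_spec`.
#' @export
hg19_genome <- function() {
  lengths <- c(
    249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
    159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
    115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
     59128983,  63025520,  48129895,  51304566)
  centromeres <- c(
    125.0e6,  93.3e6,  91.0e6,  50.4e6,  48.4e6,  61.0e6,
     59.9e6,  45.6e6,  49.0e6,  40.2e6,  53.7e6,  35.8e6,
     17.9e6,  17.6e6,  19.0e6,  36.6e6,  24.0e6,  17.2e6,
     26.5e6,  27.5e6,  13.2e6,  14.7e6)
  genome_spec(lengths, centromeres)
}

stopifnot_genome <- function(genome) {
  if (!inherits(genome, "genome_spec"))
    stop("'genome' must be a genome_spec")
  invisible(genome)
}
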