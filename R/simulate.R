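#' Simulate probe log2-ratio profiles from a truth set
#'
#' Forward model for the measured log2 ratio: a probe covered by a CNV
#' of copy change `delta` (+1 gain, -1 loss) has mean
#' `log2((2 + purity * delta) / 2)` (so +0.585 for a clonal single-copy
#' gain and -1 for a clonal single-copy loss), 0 elsewhere, with i.i.d.
#' Gaussian noise of standard deviation `noise_sd` added.  cnLOH leaves
#' the log2 ratio untouched (it only affects the SNP allele channel,
#' see [simulate_snp_homozygosity()]).
#'
#' @param truth a `cnv_truth` from [generate_cohort_truth()].
#' @param probe_map the probe map the truth was generated on.
#' @param noise_sd noise standard deviation in log2 units (>= 0).
#' @param purity tumor purity in (0, 1].
#' @param seed integer seed.
#' @return numeric matrix, samples x probes.
#' @export
simulate_l2r_profiles <- function(truth, probe_map,
                                  noise_sd = truth$config$noise_sd,
                                  purity = truth$config$purity, seed = 1L) {
  if (!inherits(truth, "cnv_truth")) stop("'truth' must be a cnv_truth")
  stopifnot_probe_map(probe_map)
  if (!identical(colnames(truth$state_matrix), probe_map$probe_id))
    stop("truth and probe map disagree on probe identity")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  bad <- vapply(truth$events,
                function(e) nrow(e) > 0 && any(!e$chrom %in% 1:22),
                logical(1))
  if (any(bad)) stop("truth events reference unknown chromosomes")
  set.seed(as.integer(seed))
  mu <- log2((2 + purity * truth$state_matrix) / 2)
  noise <- matrix(rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))
  out <- mu + noise
  dimnames(out) <- dimnames(truth$state_matrix)
  out
}

#' Simulate SNP-probe homozygosity calls
#'
#' B-allele-frequency surrogate: each SNP probe is called homozygous
#' with baseline probability `p_hom` (population heterozygosity), or
#' with probability `p_hom_loh` when it falls inside a cnLOH interval or
#' a deleted region (both produce runs of homozygosity).
#'
#' @param truth a `cnv_truth`.
#' @param probe_map probe map; only `class == "SNP"` probes are used.
#' @param p_hom baseline homozygous-call probability.
#' @param p_hom_loh homozygous-call probability under LOH.
#' @param seed integer seed.
#' @return logical matrix, samples x SNP probes (columns named by
#'   probe id).
#' @export
simulate_snp_homozygosity <- function(truth, probe_map, p_hom = 1 / 3,
                                      p_hom_loh = 0.98, seed = 1L) {
  if (!inherits(truth, "cnv_truth")) stop("'truth' must be a cnv_truth")
  stopifnot_probe_map(probe_map)
  set.seed(as.integer(seed))
  snp <- probe_map[probe_map$class == "SNP", , drop = FALSE]
  ids <- rownames(truth$state_matrix)
  out <- matrix(FALSE, length(ids), nrow(snp),
                dimnames = list(ids, snp$probe_id))
  for (i in seq_along(ids)) {
    p <- rep(p_hom, nrow(snp))
    iv <- truth$loh[[i]]
    if (nrow(iv)) for (r in seq_len(nrow(iv))) {
      hit <- snp$chrom == iv$chrom[r] & snp$pos >= iv$start[r] &
        snp$pos <= iv$end[r]
      p[hit] <- p_hom_loh
    }
    ev <- truth$events[[i]]
    del <- ev[ev$state == -1L, , drop = FALSE]
    if (nrow(del)) for (r in seq_len(nrow(del))) {
      hit <- snp$chrom == del$chrom[r] & snp$pos >= del$start[r] &
        snp$pos <= del$end[r]
      p[hit] <- p_hom_loh
    }
    out[i, ] <- runif(nrow(snp)) < p
  }
  out
}

#' Generate a synthetic gene annotation
#'
#' Random non-overlapping-ish gene intervals across the autosomes, used
#' for CNV-to-gene mapping and expression simulation.  Intervals are
#' 1-based inclusive internally; use [write_bed()] / [read_bed()] for
#' the 0-based half-open on-disk convention.
#'
#' @param genome a [genome_spec()].
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   sorted by (chrom, start).
#' @export
generate_gene_annotation <- function(genome, n_genes = 2000L, seed = 1L) {
  stopifnot_genome(genome)
  set.seed(as.integer(seed))
  chrom <- sample.int(22L, n_genes, TRUE, prob = genome$length)
  len <- pmin(round(rlnorm(n_genes, log(3e4), 1)), 2e6)
  start <- floor(runif(n_genes, 1, genome$length[chrom] - len))
  out <- data.frame(gene = sprintf("GENE%05d", seq_len(n_genes)),
                    chrom = chrom, start = start, end = start + len)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Write / read gene intervals as BED
#'
#' On disk: 0-based half-open (chrom, start, end, name).  In memory:
#' 1-based inclusive.
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`.
#' @param path file path.
#' @export
write_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- tryCatch(
    as.data.frame(data.table::fread(path, sep = "\t", header = FALSE)),
    error = function(e) stop("malformed BED file: ", conditionMessage(e)))
  if (ncol(bed) < 4L) stop("malformed BED: expected >= 4 columns")
  bad <- which(!is.finite(bed[[2]]) | !is.finite(bed[[3]]) |
                 bed[[2]] < 0 | bed[[3]] <= bed[[2]])
  if (length(bad))
    stop("malformed BED interval at line ", bad[1])
  out <- data.frame(gene = as.character(bed[[4]]), chrom = bed[[1]],
                    start = bed[[2]] + 1L, end = bed[[3]])
  out[order(out$chrom, out$start), ]
}

#' Simulate a dosage-linked expression matrix
#'
#' Baseline log-normal expression per gene; genes inside gained or lost
#' regions are scaled by the copy-dosage factor `(2 + delta) / 2`;
#' designated recurrence-linked genes are additionally scaled by their
#' effect size in recurrent samples.  Multiplicative log-normal noise.
#'
#' @param truth a `cnv_truth`.
#' @param genes gene annotation (see [generate_gene_annotation()]).
#' @param samples sample ids to simulate (default: lactotroph tumors).
#' @param de_genes character vector of recurrence-linked gene ids.
#' @param de_effect fold-change applied to `de_genes` in recurrent
#'   samples (> 0).
#' @param noise_sd log2-scale noise standard deviation.
#' @param seed integer seed.
#' @return numeric matrix, genes x samples, linear scale, non-negative.
#' @export
simulate_expression <- function(truth, genes, samples = NULL,
                                de_genes = character(), de_effect = 2,
                                noise_sd = 0.25, seed = 1L) {
  if (!inherits(truth, "cnv_truth")) stop("'truth' must be a cnv_truth")
  if (length(de_genes) && !all(de_genes %in% genes$gene))
    stop("unknown gene(s) in de_genes: ",
         paste(setdiff(de_genes, genes$gene), collapse = ", "))
  if (de_effect <= 0) stop("effect sizes must be > 0")
  set.seed(as.integer(seed))
  cl <- truth$clinical
  if (is.null(samples))
    samples <- cl$sample_id[cl$tumor_type == "lactotroph"]
  if (!all(samples %in% cl$sample_id)) stop("unknown sample id(s)")
  rec <- setNames(cl$recurrence, cl$sample_id)[samples]

  n_g <- nrow(genes)
  base <- 2^rnorm(n_g, 6, 1.5)
  expr <- matrix(rep(base, length(samples)), n_g, length(samples),
                 dimnames = list(genes$gene, samples))
  for (s in samples) {
    ev <- truth$events[[s]]
    if (nrow(ev)) for (r in seq_len(nrow(ev))) {
      hit <- genes$chrom == ev$chrom[r] & genes$start <= ev$end[r] &
        genes$end >= ev$start[r]
      expr[hit, s] <- expr[hit, s] * (2 + ev$state[r]) / 2
    }
  }
  if (length(de_genes) && any(rec == 1))
    expr[de_genes, rec == 1] <- expr[de_genes, rec == 1] * de_effect
  expr <- expr * 2^matrix(rnorm(length(expr), 0, noise_sd), n_g)
  expr
}
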