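#' Per-tumor genomic instability summaries
#'
#' Fractions are exact probe-count ratios: altered = (deleted + gained)
#' probes over total probes, with per-direction fractions reported
#' separately and cnLOH tracked on its own (it is only pooled into
#' "altered" when explicitly requested downstream).
#'
#' @param matrix alteration matrix (samples x probes, -1/0/+1).
#' @param loh_matrix optional logical cnLOH matrix of the same shape.
#' @return data.frame with one row per sample: `sample_id`,
#'   `altered_count`, `gained_count`, `deleted_count`, `loh_count`,
#'   `altered_frac`, `gained_frac`, `deleted_frac`, `loh_frac`,
#'   `altered` (flag, >= 1 altered probe).
#' @export
alteration_fractions <- function(matrix, loh_matrix = NULL) {
  if (is.null(dim(matrix)) || ncol(matrix) == 0L)
    stop("invalid input: alteration matrix has no probes")
  n <- ncol(matrix)
  gained <- rowSums(matrix == 1L)
  deleted <- rowSums(matrix == -1L)
  loh <- if (is.null(loh_matrix)) rep(0L, nrow(matrix)) else
    rowSums(loh_matrix)
  data.frame(
    sample_id = rownames(matrix),
    altered_count = gained + deleted,
    gained_count = gained, deleted_count = deleted, loh_count = loh,
    altered_frac = (gained + deleted) / n,
    gained_frac = gained / n, deleted_frac = deleted / n,
    loh_frac = loh / n,
    altered = (gained + deleted) > 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Whole-chromosome and whole-arm alteration events
#'
#' Declares a whole-chromosome (resp. arm) gain or loss when at least
#' `threshold` of that unit's probes share the direction.  A
#' whole-chromosome declaration suppresses the two arm declarations of
#' the same direction on that chromosome.
#'
#' @param matrix alteration matrix (samples x probes).
#' @param probe_map probe map.
#' @param genome [genome_spec()] supplying arm boundaries.
#' @param threshold covered-probe fraction required (default 0.9).
#' @return data.frame `sample_id`, `chrom`, `scope`
#'   (`"chromosome"`/`"p"`/`"q"`), `direction`, `covered_frac`.
#' @export
summarize_large_events <- function(matrix, probe_map, genome,
                                   threshold = 0.9) {
  stopifnot_probe_map(probe_map)
  stopifnot_genome(genome)
  if (!all(probe_map$chrom %in% genome$chrom))
    stop("probe map references chromosomes absent from the genome spec")
  rows <- list()
  add <- function(s, ci, scope, dir, frac)
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = s, chrom = ci, scope = scope, direction = dir,
      covered_frac = frac, stringsAsFactors = FALSE)
  for (ci in unique(probe_map$chrom)) {
    sel <- probe_map$chrom == ci
    cen <- genome$centromere[genome$chrom == ci]
    p_arm <- sel & probe_map$pos < cen
    q_arm <- sel & probe_map$pos >= cen
    for (dir in c("gain", "loss")) {
      v <- if (dir == "gain") 1L else -1L
      frac_chr <- rowMeans(matrix[, sel, drop = FALSE] == v)
      for (s in seq_len(nrow(matrix))) {
        sid <- rownames(matrix)[s]
        if (frac_chr[s] >= threshold) {
          add(sid, ci, "chromosome", dir, frac_chr[s])
        } else {
          if (sum(p_arm) > 0) {
            fp <- mean(matrix[s, p_arm] == v)
            if (fp >= threshold) add(sid, ci, "p", dir, fp)
          }
          if (sum(q_arm) > 0) {
            fq <- mean(matrix[s, q_arm] == v)
            if (fq >= threshold) add(sid, ci, "q", dir, fq)
          }
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chrom = integer(),
               scope = character(), direction = character(),
               covered_frac = numeric())
}

## Exact Kruskal-Wallis permutation p by enumeration of distinct group
## assignments (combined n <= 10).
kw_exact_p <- function(values, groups) {
  g <- as.factor(groups)
  obs <- suppressWarnings(kruskal.test(values, g)$statistic)
  n <- length(values)
  counts <- table(g)
  stat_of <- function(lab) suppressWarnings(kruskal.test(values,
    factor(lab, levels = levels(g)))$statistic)
  labs <- levels(g)
  acc <- new.env()
  acc$num <- 0; acc$den <- 0
  assign_rec <- function(remaining, lab_idx, labels) {
    if (lab_idx == length(labs)) {
      labels[remaining] <- labs[lab_idx]
      acc$den <- acc$den + 1
      if (stat_of(labels) >= obs - 1e-10) acc$num <- acc$num + 1
      return(invisible(NULL))
    }
    k <- counts[[lab_idx]]
    cmb <- utils::combn(remaining, k)
    for (col in seq_len(ncol(cmb))) {
      labels2 <- labels
      labels2[cmb[, col]] <- labs[lab_idx]
      assign_rec(setdiff(remaining, cmb[, col]), lab_idx + 1L, labels2)
    }
  }
  assign_rec(seq_len(n), 1L, character(n))
  acc$num / acc$den
}

#' Rank-based group comparison of instability burden
#'
#' Two groups: Wilcoxon rank-sum (exact when the combined n is <= 10
#' and there are no ties, otherwise the normal approximation with tie
#' correction).  More than two groups, or `test = "kruskal"`:
#' Kruskal-Wallis, with the p-value by exact enumeration of group
#' assignments when the combined n is <= 10.
#'
#' @param values numeric vector (e.g. altered fractions).
#' @param groups grouping vector, >= 2 non-empty groups.
#' @param test `"auto"` (Wilcoxon for 2 groups, Kruskal-Wallis
#'   otherwise), `"wilcoxon"`, or `"kruskal"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
group_compare <- function(values, groups, test = c("auto", "wilcoxon",
                                                   "kruskal")) {
  test <- match.arg(test)
  g <- factor(groups)
  if (nlevels(g) < 2L || any(table(g) == 0L))
    stop("invalid grouping: need >= 2 non-empty groups")
  n <- length(values)
  two <- nlevels(g) == 2L
  if (test == "wilcoxon" && !two)
    stop("wilcoxon requires exactly 2 groups")
  use_wilcox <- (test == "wilcoxon") || (test == "auto" && two)
  if (use_wilcox) {
    exact <- n <= 10L && !anyDuplicated(values)
    wt <- suppressWarnings(wilcox.test(values ~ g, exact = exact,
                                       correct = !exact))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact) "wilcoxon-exact" else "wilcoxon-normal")
  } else {
    kt <- suppressWarnings(kruskal.test(values, g))
    if (n <= 10L)
      list(statistic = unname(kt$statistic),
           p_value = kw_exact_p(values, g),
           method = "kruskal-exact")
    else
      list(statistic = unname(kt$statistic), p_value = kt$p.value,
           method = "kruskal-chisq")
  }
}
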