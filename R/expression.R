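#' Differential expression between recurrent and non-recurrent tumors
#'
#' Fold change is the ratio of group means on the linear scale,
#' sign-encoded: `+x` means x-fold higher in the recurrent group, `-x`
#' means x-fold lower (so `|signed FC| >= 1` by construction).  The
#' test is a two-sided equal-variance Student t-test on log2 values.
#' A gene is flagged differentially expressed when `|FC| >= fc_min`
#' and `p <= p_max` (both boundaries inclusive).
#'
#' @param expr genes x samples matrix of non-negative linear-scale
#'   values.
#' @param groups vector over samples with levels `"recurrent"` /
#'   `"non_recurrent"` (or any two labels; the first level of
#'   `factor(groups)` after reordering below is the reference).
#' @param recurrent_label label identifying the recurrent group.
#' @param fc_min,p_max DE thresholds (defaults 2 and 0.05).
#' @return data.frame `gene`, `fc` (signed), `t_stat`, `p_value`,
#'   `de` (flag), `flag` (`"zero_mean"` when a group mean is 0, such
#'   genes are excluded from DE).
#' @export
differential_expression <- function(expr, groups,
                                    recurrent_label = "recurrent",
                                    fc_min = 2, p_max = 0.05) {
  g <- groups == recurrent_label
  if (sum(g) < 2L || sum(!g) < 2L)
    stop("need >= 2 samples per group")
  if (any(expr < 0)) stop("expression values must be non-negative")
  m1 <- rowMeans(expr[, g, drop = FALSE])
  m0 <- rowMeans(expr[, !g, drop = FALSE])
  ratio <- m1 / m0
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  lx <- log2(pmax(expr, min(expr[expr > 0], 1e-9) / 2))
  t_stat <- p <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    tt <- tryCatch(t.test(lx[i, g], lx[i, !g], var.equal = TRUE),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    t_stat[i] <- unname(tt$statistic)
    p[i] <- tt$p.value
  }
  zero <- m0 == 0 | m1 == 0
  out <- data.frame(gene = rownames(expr), fc = fc, t_stat = t_stat,
                    p_value = p,
                    de = !zero & abs(fc) >= fc_min & !is.na(p) &
                      p <= p_max,
                    flag = ifelse(zero, "zero_mean", ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$fc[zero] <- NA_real_
  out
}

#' Signal-to-noise gene ranking
#'
#' `s2n = (mu_rec - mu_non) / (sd_rec + sd_non)` per gene, with each
#' group's standard deviation floored at `0.2 * |mean|` (and at 0.2
#' when the mean is 0), the canonical GSEA convention keeping the
#' metric finite.  Genes are returned in descending metric order; ties
#' break by gene id.
#'
#' @inheritParams differential_expression
#' @param sd_floor_frac the variance-floor fraction (set 0 to disable).
#' @return data.frame `gene`, `s2n`, ordered; usable directly by
#'   [gsea_preranked()].
#' @export
signal_to_noise_ranking <- function(expr, groups,
                                    recurrent_label = "recurrent",
                                    sd_floor_frac = 0.2) {
  g <- groups == recurrent_label
  if (sum(g) < 2L || sum(!g) < 2L)
    stop("undefined standard deviation: need >= 2 samples per group")
  floor_sd <- function(s, m) {
    if (sd_floor_frac <= 0) return(s)
    s <- pmax(s, sd_floor_frac * abs(m))
    ifelse(s == 0, sd_floor_frac, s)
  }
  m1 <- rowMeans(expr[, g, drop = FALSE])
  m0 <- rowMeans(expr[, !g, drop = FALSE])
  s1 <- floor_sd(apply(expr[, g, drop = FALSE], 1, sd), m1)
  s0 <- floor_sd(apply(expr[, !g, drop = FALSE], 1, sd), m0)
  s2n <- (m1 - m0) / (s1 + s0)
  out <- data.frame(gene = rownames(expr), s2n = s2n, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$s2n, out$gene), , drop = FALSE]
}

## Weighted Kolmogorov-Smirnov running-sum enrichment score.
gsea_es <- function(ranked_genes, metric, set, weight = 1) {
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  N <- length(ranked_genes)
  w <- abs(metric)^weight
  denom <- sum(w[hit])
  inc <- if (denom > 0) w * hit / denom else hit / max(nh, 1)
  dec <- (!hit) / (N - nh)
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Read a GMT gene-set file
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running sum over the ranked list (hit
#' increments proportional to `|metric|^weight` with `weight = 1`,
#' miss decrement `1/(N - Nh)`); ES is the maximum deviation.  The
#' null is by gene-set-label permutation: `n_perm` random sets of the
#' same size drawn from the ranked list.  NES divides ES by the mean
#' |null ES| of the same sign; the nominal p-value is one-sided within
#' sign; FDR q uses the ratio-of-tails estimator over the pooled null
#' NES.  Sets with fewer than 2 member genes present in the list are
#' skipped with a flag.
#'
#' @param ranked data.frame from [signal_to_noise_ranking()] (columns
#'   `gene`, metric in the second column), already ordered.
#' @param gene_sets named list of character vectors (see
#'   [read_gmt()]).
#' @param n_perm number of permutations (default 1000).
#' @param weight exponent on |metric| for hit increments (default 1).
#' @param seed integer seed.
#' @param p_max,q_max significance thresholds for the `significant`
#'   flag (defaults 0.05 and 0.25).
#' @return data.frame `set`, `size`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `significant`, `flag`.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000L,
                           weight = 1, seed = 1L,
                           p_max = 0.05, q_max = 0.25) {
  set.seed(as.integer(seed))
  genes <- ranked$gene
  metric <- ranked[[2]]
  res <- data.frame(set = names(gene_sets),
                    size = NA_integer_, es = NA_real_, nes = NA_real_,
                    p_value = NA_real_, fdr_q = NA_real_,
                    significant = FALSE, flag = "",
                    stringsAsFactors = FALSE)
  null_nes <- list()
  obs_nes <- rep(NA_real_, length(gene_sets))
  null_by_set <- vector("list", length(gene_sets))
  for (k in seq_along(gene_sets)) {
    members <- intersect(gene_sets[[k]], genes)
    res$size[k] <- length(members)
    if (length(members) < 2L) {
      res$flag[k] <- "too_small"
      next
    }
    es <- gsea_es(genes, metric, members, weight)
    null_es <- vapply(seq_len(n_perm), function(b)
      gsea_es(genes, metric, sample(genes, length(members)), weight),
      numeric(1))
    pos <- null_es[null_es >= 0]
    neg <- null_es[null_es < 0]
    if (es >= 0) {
      denom <- if (length(pos)) mean(pos) else NA_real_
      res$p_value[k] <- (1 + sum(pos >= es)) / (1 + length(pos))
    } else {
      denom <- if (length(neg)) mean(abs(neg)) else NA_real_
      res$p_value[k] <- (1 + sum(neg <= es)) / (1 + length(neg))
    }
    res$es[k] <- es
    res$nes[k] <- es / denom
    obs_nes[k] <- res$nes[k]
    null_by_set[[k]] <- c(pos / (if (length(pos)) mean(pos) else NA),
                          neg / (if (length(neg)) mean(abs(neg)) else NA))
  }
  pooled <- unlist(null_by_set)
  for (k in seq_along(gene_sets)) {
    nes <- obs_nes[k]
    if (is.na(nes)) next
    if (nes >= 0) {
      tail_null <- mean(pooled >= nes, na.rm = TRUE)
      tail_obs <- mean(obs_nes >= nes, na.rm = TRUE)
    } else {
      tail_null <- mean(pooled <= nes, na.rm = TRUE)
      tail_obs <- mean(obs_nes <= nes, na.rm = TRUE)
    }
    res$fdr_q[k] <- min(1, tail_null / max(tail_obs, 1e-12))
  }
  res$significant <- !is.na(res$p_value) & res$p_value < p_max &
    !is.na(res$fdr_q) & res$fdr_q < q_max
  res
}

#' Intersect CNV-associated genes with differential expression
#'
#' Rows are genes significant in the per-gene CNV scan (adjusted
#' p < `alpha`, univariate or multivariate) that are also flagged
#' differentially expressed, with separate membership flags for the
#' univariate- and multivariate-derived lists.
#'
#' @param gene_scan per-gene scan table from [per_gene_scan()].
#' @param de DE table from [differential_expression()].
#' @param alpha adjusted-p threshold for CNV significance.
#' @param max_mismatch maximum tolerated fraction of scan genes absent
#'   from the DE table before the join is refused.
#' @return data.frame `gene`, `chrom`, `p_uni`, `p_adj_uni`,
#'   `p_multi`, `p_adj_multi`, `fc`, `t_test_p`, `in_univariate`,
#'   `in_multivariate`.
#' @export
integrate_cnv_expression <- function(gene_scan, de, alpha = 0.05,
                                     max_mismatch = 0.5) {
  shared <- intersect(gene_scan$gene, de$gene)
  tested <- gene_scan[!is.na(gene_scan$p_adj_uni) |
                        !is.na(gene_scan$p_adj_multi), ]
  if (nrow(tested) > 0 && nrow(de) > 0) {
    miss <- mean(!tested$gene %in% de$gene)
    if (miss > max_mismatch)
      stop(sprintf(
        "gene identifier mismatch: %.0f%% of scanned genes missing from the expression table",
        100 * miss))
  }
  sc <- gene_scan[gene_scan$gene %in% shared, ]
  dd <- de[match(sc$gene, de$gene), ]
  in_uni <- !is.na(sc$p_adj_uni) & sc$p_adj_uni < alpha & dd$de
  in_mul <- !is.na(sc$p_adj_multi) & sc$p_adj_multi < alpha & dd$de
  keep <- in_uni | in_mul
  data.frame(gene = sc$gene[keep], chrom = sc$chrom[keep],
             p_uni = sc$p_uni[keep], p_adj_uni = sc$p_adj_uni[keep],
             p_multi = sc$p_multi[keep],
             p_adj_multi = sc$p_adj_multi[keep],
             fc = dd$fc[keep], t_test_p = dd$p_value[keep],
             in_univariate = in_uni[keep],
             in_multivariate = in_mul[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
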