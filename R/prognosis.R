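## Covariate design for recurrence models.  Whole-cohort scope adjusts
## for tumor type, grade, age and sex; per-type scopes drop the type
## term and merge grades 1a and 1b (few 1b tumors per type).
prognosis_design <- function(clinical, scope, adjusted) {
  if (!adjusted) return(data.frame(row.names = seq_len(nrow(clinical))))
  grade <- as.character(clinical$grade)
  if (scope != "cohort")
    grade[grade %in% c("1a", "1b")] <- "1ab"
  d <- data.frame(grade = factor(grade), age = clinical$age,
                  sex = factor(clinical$sex))
  if (scope == "cohort")
    d$tumor_type <- factor(clinical$tumor_type)
  ## drop covariates that are constant in scope (e.g. single grade)
  keep <- vapply(d, function(col) length(unique(col)) > 1L, logical(1))
  d[, keep, drop = FALSE]
}

scope_rows <- function(clinical, scope) {
  if (scope == "cohort") seq_len(nrow(clinical))
  else which(clinical$tumor_type == scope)
}

#' Burden-recurrence association
#'
#' Logistic regression of 5-year recurrence on instability burden,
#' entered as `log2(altered probe count + pseudo)` so `exp(beta)` is
#' the odds ratio per doubling of altered probes.  Significance is by
#' likelihood-ratio test against the model without the burden term;
#' the OR confidence interval is Wald.  Multivariate fits adjust for
#' tumor type (whole cohort only), grade (1a+1b merged within type),
#' age and sex.
#'
#' @param summaries instability table from [alteration_fractions()].
#' @param clinical clinical table aligned by `sample_id`.
#' @param scope `"cohort"` or a tumor type name.
#' @param adjusted add the clinical covariates (multivariate) or not.
#' @param measure burden measure: `"altered"`, `"gained"`, `"deleted"`,
#'   `"loh"`, or `"altered_plus_loh"` (CNV and cnLOH probes pooled).
#' @param pseudo pseudo-count added before the log2 (default 1).
#' @return one-row data.frame: `predictor`, `scope`, `or`, `ci_lo`,
#'   `ci_hi` (95% Wald), `lrt_stat`, `df`, `p_value`, `n`, `flag`
#'   (`"low_n"` below 10 samples, `"separation"`, or `""`).
#' @export
burden_association <- function(summaries, clinical, scope = "cohort",
                               adjusted = TRUE, measure = "altered",
                               pseudo = 1) {
  m <- match(summaries$sample_id, clinical$sample_id)
  if (any(is.na(m))) stop("summaries and clinical table not aligned")
  cl <- clinical[m, ]
  rows <- scope_rows(cl, scope)
  cl <- cl[rows, ]
  counts <- switch(measure,
    altered = summaries$altered_count,
    gained = summaries$gained_count,
    deleted = summaries$deleted_count,
    loh = summaries$loh_count,
    altered_plus_loh = summaries$altered_count + summaries$loh_count,
    stop("unknown burden measure"))[rows]
  y <- cl$recurrence
  if (length(unique(y)) < 2L)
    stop("scope has a single outcome class")
  burden <- log2(counts + pseudo)
  base <- prognosis_design(cl, scope, adjusted)
  flag <- if (length(y) < 10L) "low_n" else ""

  if (length(unique(burden)) < 2L) {
    return(data.frame(predictor = paste0("log2_", measure, "_probes"),
                      scope = scope, or = 1, ci_lo = NA_real_,
                      ci_hi = NA_real_, lrt_stat = 0, df = 0L,
                      p_value = 1, n = length(y), flag = flag))
  }
  full <- fit_logistic(y, cbind(base, burden = burden))
  reduced <- if (ncol(base)) fit_logistic(y, base)
             else fit_logistic(y, data.frame(.const = rep(1, length(y))))
  lrt <- likelihood_ratio_test(full, reduced)
  b <- full$coef[["burden"]]
  se <- full$se[["burden"]]
  if (full$separated) flag <- paste0(flag, if (nzchar(flag)) "+",
                                     "separation")
  data.frame(predictor = paste0("log2_", measure, "_probes"),
             scope = scope, or = exp(b),
             ci_lo = exp(b - qnorm(0.975) * se),
             ci_hi = exp(b + qnorm(0.975) * se),
             lrt_stat = lrt$statistic, df = lrt$df,
             p_value = lrt$p_value, n = length(y), flag = flag,
             stringsAsFactors = FALSE)
}

## Fast nested binomial fits via glm.fit on prebuilt model matrices;
## deviance difference is the LRT statistic.
glmfit_dev <- function(X, y) {
  f <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 100)))
  list(dev = f$deviance, coef = f$coefficients,
       separated = (any(f$fitted.values < 1e-8) ||
                      any(f$fitted.values > 1 - 1e-8)) &&
         any(abs(f$coefficients) > 10, na.rm = TRUE))
}

#' Genome-wide per-probe recurrence scan
#'
#' For each probe, a logistic model of recurrence on the probe's
#' three-level status (deleted / normal / gained; reference "normal",
#' so the test has df = number of non-reference levels observed at the
#' probe), compared by likelihood-ratio test with the model without the
#' probe term.  P-values are adjusted for dependent multiple testing by
#' Benjamini-Yekutieli over the actually tested (non-constant) probes;
#' skipped probes are retained with a `"constant"` flag, separation
#' becomes a per-probe flag.
#'
#' @param matrix alteration matrix (samples x probes).
#' @param clinical clinical table.
#' @param scope `"cohort"` or a tumor type.
#' @param adjusted include the clinical covariates.
#' @return data.frame per probe: `probe_id`, `n_del`, `n_norm`,
#'   `n_gain`, `or_del`, `or_gain`, `lrt_stat`, `df`, `p_value`,
#'   `p_adj` (BY), `flag`.
#' @export
per_probe_scan <- function(matrix, clinical, scope = "cohort",
                           adjusted = TRUE) {
  m <- match(rownames(matrix), clinical$sample_id)
  if (any(is.na(m))) stop("matrix and clinical table not aligned")
  cl <- clinical[m, ]
  rows <- scope_rows(cl, scope)
  cl <- cl[rows, ]
  mat <- matrix[rows, , drop = FALSE]
  y <- cl$recurrence
  if (length(unique(y)) < 2L) stop("scope has a single outcome class")
  base <- prognosis_design(cl, scope, adjusted)
  Xbase <- if (ncol(base)) model.matrix(~ ., base)
           else stats::model.matrix(~ 1, data.frame(y = y))
  red <- glmfit_dev(Xbase, y)

  n_probes <- ncol(mat)
  out <- data.frame(
    probe_id = colnames(mat),
    n_del = integer(n_probes), n_norm = integer(n_probes),
    n_gain = integer(n_probes),
    or_del = NA_real_, or_gain = NA_real_,
    lrt_stat = NA_real_, df = NA_integer_, p_value = NA_real_,
    p_adj = NA_real_, flag = "", stringsAsFactors = FALSE)
  for (p in seq_len(n_probes)) {
    st <- mat[, p]
    out$n_del[p] <- sum(st == -1L)
    out$n_norm[p] <- sum(st == 0L)
    out$n_gain[p] <- sum(st == 1L)
    lev <- sort(unique(st))
    if (length(lev) < 2L) {
      out$flag[p] <- "constant"
      next
    }
    extra <- NULL
    if (-1L %in% lev) extra <- cbind(extra, del = as.numeric(st == -1L))
    if (1L %in% lev) extra <- cbind(extra, gain = as.numeric(st == 1L))
    if (!0L %in% lev) extra <- extra[, -1L, drop = FALSE]  # avoid collinearity
    ful <- glmfit_dev(cbind(Xbase, extra), y)
    stat <- max(red$dev - ful$dev, 0)
    df <- ncol(extra)
    out$lrt_stat[p] <- stat
    out$df[p] <- df
    out$p_value[p] <- pchisq(stat, df, lower.tail = FALSE)
    cf <- ful$coef
    if ("del" %in% names(cf)) out$or_del[p] <- exp(cf[["del"]])
    if ("gain" %in% names(cf)) out$or_gain[p] <- exp(cf[["gain"]])
    if (ful$separated) out$flag[p] <- "separation"
  }
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- adjust_pvalues(out$p_value[tested], "BY")
  out
}

#' Map CNV segments to gene alteration states
#'
#' Each gene takes, per sample, the state of the altered segment(s)
#' overlapping it (any overlap counts).  A gene spanning both gained
#' and lost segments in one sample takes the state of the larger
#' overlapped fraction (exact ties resolve to gain) and is flagged
#' ambiguous-altered.
#'
#' @param segment_sets named list (by sample) of state-called segment
#'   tables.
#' @param genes gene annotation (1-based inclusive; see [read_bed()]
#'   for BED input).
#' @return integer matrix genes x samples in {-1, 0, +1} with
#'   attributes `gene_info` (the annotation) and `ambiguous` (logical
#'   matrix of tie flags).
#' @export
map_genes_to_status <- function(segment_sets, genes) {
  gr_genes <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(genes$start, genes$end))
  n_g <- nrow(genes)
  out <- matrix(0L, n_g, length(segment_sets),
                dimnames = list(genes$gene, names(segment_sets)))
  amb <- matrix(FALSE, n_g, length(segment_sets),
                dimnames = dimnames(out))
  for (i in seq_along(segment_sets)) {
    seg <- segment_sets[[i]]
    alt <- seg[seg$state != "neutral", , drop = FALSE]
    if (!nrow(alt)) next
    gr_seg <- GenomicRanges::GRanges(
      seqnames = as.character(alt$chrom),
      ranges = IRanges::IRanges(alt$start_pos, alt$end_pos))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_genes)[S4Vectors::queryHits(hits)],
      IRanges::ranges(gr_seg)[S4Vectors::subjectHits(hits)]))
    st <- ifelse(alt$state[S4Vectors::subjectHits(hits)] == "gain", 1L,
                 -1L)
    qh <- S4Vectors::queryHits(hits)
    gain_w <- tapply(ov * (st == 1L), qh, sum)
    loss_w <- tapply(ov * (st == -1L), qh, sum)
    gidx <- as.integer(names(gain_w))
    state <- ifelse(gain_w > loss_w, 1L,
                    ifelse(loss_w > gain_w, -1L, 1L))
    out[gidx, i] <- state
    amb[gidx, i] <- gain_w > 0 & loss_w > 0   # mixed-direction overlap
  }
  attr(out, "gene_info") <- genes
  attr(out, "ambiguous") <- amb
  out
}

#' Per-gene recurrence scan
#'
#' For each gene, recurrence is regressed on the binarized gene status
#' (altered vs not) with a likelihood-ratio test, in both univariate
#' and multivariate (age, sex, grade with 1a+1b merged) forms,
#' mirroring the paired gene lists of a per-type analysis.  P-values
#' are Benjamini-Hochberg adjusted over tested genes, separately for
#' the two model forms.
#'
#' @param gene_matrix genes x samples matrix from
#'   [map_genes_to_status()].
#' @param clinical clinical table.
#' @param scope tumor type (default `"lactotroph"`) or `"cohort"`.
#' @return data.frame per gene: `gene`, `chrom`, `n_altered`,
#'   `p_uni`, `p_adj_uni`, `p_multi`, `p_adj_multi`, `flag`.
#' @export
per_gene_scan <- function(gene_matrix, clinical, scope = "lactotroph") {
  info <- attr(gene_matrix, "gene_info")
  m <- match(colnames(gene_matrix), clinical$sample_id)
  if (any(is.na(m))) stop("gene matrix and clinical table not aligned")
  cl <- clinical[m, ]
  rows <- scope_rows(cl, scope)
  cl <- cl[rows, ]
  gm <- gene_matrix[, rows, drop = FALSE]
  y <- cl$recurrence
  if (length(unique(y)) < 2L) stop("scope has a single outcome class")
  base <- prognosis_design(cl, scope, adjusted = TRUE)
  Xuni <- stats::model.matrix(~ 1, data.frame(y = y))
  Xmul <- model.matrix(~ ., base)
  red_uni <- glmfit_dev(Xuni, y)
  red_mul <- glmfit_dev(Xmul, y)

  n_g <- nrow(gm)
  out <- data.frame(gene = rownames(gm),
                    chrom = if (!is.null(info))
                      info$chrom[match(rownames(gm), info$gene)] else NA,
                    n_altered = integer(n_g),
                    p_uni = NA_real_, p_adj_uni = NA_real_,
                    p_multi = NA_real_, p_adj_multi = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (g in seq_len(n_g)) {
    alt <- as.numeric(gm[g, ] != 0L)
    out$n_altered[g] <- sum(alt)
    if (length(unique(alt)) < 2L) {
      out$flag[g] <- "constant"
      next
    }
    fu <- glmfit_dev(cbind(Xuni, alt = alt), y)
    fm <- glmfit_dev(cbind(Xmul, alt = alt), y)
    out$p_uni[g] <- pchisq(max(red_uni$dev - fu$dev, 0), 1,
                           lower.tail = FALSE)
    out$p_multi[g] <- pchisq(max(red_mul$dev - fm$dev, 0), 1,
                             lower.tail = FALSE)
    if (fu$separated || fm$separated) out$flag[g] <- "separation"
  }
  tested <- !is.na(out$p_uni)
  out$p_adj_uni[tested] <- adjust_pvalues(out$p_uni[tested], "BH")
  out$p_adj_multi[tested] <- adjust_pvalues(out$p_multi[tested], "BH")
  out
}
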