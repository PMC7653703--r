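#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper around `stats::glm` (iteratively reweighted least
#' squares, deviance convergence tolerance 1e-8) that detects and flags
#' complete or quasi-complete separation instead of reporting it
#' silently: a fit is flagged when fitted probabilities reach 0/1 to
#' machine precision together with a diverging coefficient.
#'
#' @param outcome binary 0/1 vector.
#' @param design data.frame of covariates (factors and numerics).
#' @return list of class `cnv_logit`: `model` (the glm), `coef`, `se`,
#'   `loglik`, `deviance`, `n`, `separated` (flag).
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% 0:1)) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2L)
    stop("invalid input: outcome has a single class")
  dat <- cbind(data.frame(.y = outcome), design)
  if (nrow(dat) <= ncol(stats::model.matrix(~ ., design)))
    stop("more parameters than observations")
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial(),
                              control = stats::glm.control(
                                epsilon = 1e-8, maxit = 100)))
  sm <- suppressWarnings(summary(fit))
  mu <- fit$fitted.values
  separated <- (any(mu < 1e-8) || any(mu > 1 - 1e-8)) &&
    any(abs(coef(fit)) > 10, na.rm = TRUE)
  out <- list(model = fit, coef = coef(fit),
              se = sm$coefficients[, "Std. Error"],
              loglik = as.numeric(logLik(fit)),
              deviance = fit$deviance, n = length(outcome),
              separated = separated)
  class(out) <- c("cnv_logit", "list")
  out
}

#' Likelihood-ratio test between nested logistic models
#'
#' @param full,reduced `cnv_logit` fits on the same observations, with
#'   the reduced model's terms a subset of the full model's.
#' @return list `statistic` (`2 * (llf - llr)`, clamped at 0), `df`
#'   (parameter-count difference), `p_value` (upper chi-square tail).
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (!inherits(full, "cnv_logit") || !inherits(reduced, "cnv_logit"))
    stop("both models must be cnv_logit fits")
  if (full$n != reduced$n)
    stop("invalid comparison: models fit on different observations")
  tf <- attr(stats::terms(full$model), "term.labels")
  tr <- attr(stats::terms(reduced$model), "term.labels")
  mf <- reduced$model$model
  vacuous <- vapply(tr, function(tm)
    tm %in% names(mf) && length(unique(mf[[tm]])) <= 1L, logical(1))
  if (!all(tr %in% tf | vacuous))
    stop("invalid comparison: models are not nested")
  df <- sum(!is.na(coef(full$model))) - sum(!is.na(coef(reduced$model)))
  if (df < 0) stop("invalid comparison: reduced model is larger")
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Step-up multiple-testing adjustment (BH / BY)
#'
#' Benjamini-Hochberg, or Benjamini-Yekutieli for dependent tests
#' (step-up with the harmonic-sum inflation `c(m) = sum(1/i)`), both
#' capped at 1 and monotone in rank.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` or `"BY"`.
#' @return adjusted p-values (same length and order).
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("invalid input: p-values must be in [0, 1]")
  p.adjust(pvalues, method = method)
}
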