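test_that("logistic fits reproduce closed-form 2x2 odds ratios", {
  ## exposed 8 recurrent / 2 not; unexposed 2 / 8 -> OR = 8*8/(2*2) = 16
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  x <- c(rep(1, 10), rep(0, 10))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_equal(exp(fit$coef[["x"]]), 16, tolerance = 1e-6)
  expect_false(fit$separated)

  ## independence: all cells equal -> OR = 1
  y0 <- rep(c(1, 0), 10)
  x0 <- rep(c(1, 1, 0, 0), 5)
  fit0 <- fit_logistic(y0, data.frame(x = x0))
  expect_equal(exp(fit0$coef[["x"]]), 1, tolerance = 1e-6)

  ## large-sample recovery of a planted coefficient
  set.seed(42)
  xx <- rnorm(2000)
  yy <- rbinom(2000, 1, plogis(-0.2 + 0.5 * xx))
  fit1 <- fit_logistic(yy, data.frame(x = xx))
  expect_lt(abs(fit1$coef[["x"]] - 0.5), 0.1)

  ## complete separation is flagged, not silent
  ys <- c(rep(0, 10), rep(1, 10))
  xs <- c(rnorm(10, -3), rnorm(10, 3))
  fits <- fit_logistic(ys, data.frame(x = xs))
  expect_true(fits$separated)

  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "single class")
})

test_that("likelihood-ratio tests are calibrated and degenerate correctly", {
  set.seed(10)
  x <- rnorm(100)
  y <- rbinom(100, 1, 0.5)
  full <- fit_logistic(y, data.frame(x = x, c = rep(1, 100)))
  red <- fit_logistic(y, data.frame(x = x))
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$statistic, 0, tolerance = 1e-8)
  expect_equal(lrt$p_value, 1)

  ## strong true predictor: p below 1e-4
  set.seed(11)
  hits <- 0L
  for (s in 1:20) {
    x1 <- rnorm(500)
    y1 <- rbinom(500, 1, plogis(x1))
    f <- fit_logistic(y1, data.frame(x = x1))
    r <- fit_logistic(y1, data.frame(.const = rep(1, 500)))
    if (likelihood_ratio_test(f, r)$p_value < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 20 * 0.99)

  big <- fit_logistic(y, data.frame(x = x, z = rnorm(100)))
  expect_error(likelihood_ratio_test(red, big), "nested|larger")
})

test_that("BH and BY match hand computations and the brute-force oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BY"),
               rep(0.055, 3))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04, 0.05), "BH"),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "BY"), 0.03)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(300)
  for (r in 1:200) {
    m <- sample(1:50, 1)
    p <- runif(m)
    expect_equal(adjust_pvalues(p, "BH"), brute_step_up(p, "BH"),
                 tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "BY"), brute_step_up(p, "BY"),
                 tolerance = 1e-12)
    ## BY >= BH pointwise, both >= raw
    expect_true(all(adjust_pvalues(p, "BY") >=
                      adjust_pvalues(p, "BH") - 1e-12))
    expect_true(all(adjust_pvalues(p, "BH") >= p - 1e-12))
  }
})

test_that("burden association recovers the planted odds ratio", {
  g <- hg19_genome()
  pm <- generate_probe_map(g, 800, 0, seed = 1)
  cfg <- cohort_config(type_counts = c(lactotroph = 2000L))
  tr <- generate_cohort_truth(cfg, pm, g, seed = 50)
  summ <- alteration_fractions(tr$state_matrix)
  res <- burden_association(summ, tr$clinical, scope = "lactotroph")
  expect_gt(res$or, 1.25)
  expect_lt(res$or, 1.35)
  expect_lt(res$p_value, 0.001)
  ## Wald CI contains the estimate
  expect_true(res$ci_lo < res$or && res$or < res$ci_hi)

  ## constant burden: LRT 0, p 1
  summ_const <- summ
  summ_const$altered_count <- 5L
  res0 <- burden_association(summ_const, tr$clinical,
                             scope = "lactotroph")
  expect_equal(res0$lrt_stat, 0)
  expect_equal(res0$p_value, 1)

  ## cnLOH-free cohorts: pooled measure equals the CNV-only analysis
  res_pool <- burden_association(summ, tr$clinical, scope = "lactotroph",
                                 measure = "altered_plus_loh")
  expect_equal(res_pool$or, res$or)
  expect_equal(res_pool$p_value, res$p_value)

  ## LRT invariant to affine rescaling of the age covariate
  tr_scaled <- tr
  tr_scaled$clinical$age <- tr$clinical$age / 10 - 3
  res_sc <- burden_association(summ, tr_scaled$clinical,
                               scope = "lactotroph")
  expect_equal(res_sc$lrt_stat, res$lrt_stat, tolerance = 1e-6)
})

test_that("per-probe scans flag constants and separation, adjust by BY", {
  set.seed(61)
  n <- 60
  clin <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     tumor_type = "lactotroph",
                     grade = sample(c("1a", "2a", "2b"), n, TRUE),
                     age = rnorm(n, 47, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     recurrence = rbinom(n, 1, 0.5))
  m <- matrix(0L, n, 6,
              dimnames = list(clin$sample_id, sprintf("p%d", 1:6)))
  m[, 2] <- sample(c(-1L, 0L, 1L), n, TRUE)
  m[, 3] <- rbinom(n, 1, 0.3)
  m[, 4] <- ifelse(clin$recurrence == 1, 1L, 0L)  # separable probe
  m[, 5] <- -rbinom(n, 1, 0.2)
  scan <- per_probe_scan(m, clin, scope = "lactotroph")
  expect_equal(scan$flag[1], "constant")
  expect_true(is.na(scan$p_value[1]))
  expect_equal(scan$df[2], 2L)
  expect_equal(scan$df[3], 1L)
  expect_equal(scan$flag[4], "separation")
  expect_true(is.finite(scan$p_value[4]))         # LRT p still reported
  expect_lt(scan$p_value[4], 1e-6)
  ## BY over tested probes only, adjusted >= raw
  tested <- !is.na(scan$p_value)
  expect_equal(scan$p_adj[tested],
               adjust_pvalues(scan$p_value[tested], "BY"))
  expect_true(all(scan$p_adj[tested] >= scan$p_value[tested] - 1e-12))
})

test_that("genome-wide null scans keep the BY minimum above 0.05", {
  ok <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    n <- 50
    clin <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       tumor_type = "lactotroph",
                       grade = sample(c("1a", "2a"), n, TRUE),
                       age = rnorm(n, 47, 10),
                       sex = sample(c("F", "M"), n, TRUE),
                       recurrence = rbinom(n, 1, 0.5))
    m <- matrix(sample(c(-1L, 0L, 1L), n * 2000, TRUE,
                       prob = c(0.1, 0.8, 0.1)), n, 2000)
    dimnames(m) <- list(clin$sample_id, sprintf("p%04d", 1:2000))
    scan <- per_probe_scan(m, clin, scope = "lactotroph",
                           adjusted = FALSE)
    if (min(scan$p_adj, na.rm = TRUE) > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 9)
})

test_that("gene mapping follows the any-overlap and majority rules", {
  genes <- data.frame(gene = c("G1", "G2", "G3"), chrom = c(1, 1, 2),
                      start = c(10e6, 50e6, 10e6),
                      end = c(11e6, 60e6, 12e6))
  seg <- data.frame(chrom = c(1, 1, 1), start_idx = 1:3, end_idx = 1:3,
                    start_pos = c(9e6, 50e6, 56e6),
                    end_pos = c(12e6, 55.9e6, 70e6), n_probes = 10,
                    mean_l2r = c(0.6, -0.8, 0.6),
                    state = c("gain", "loss", "gain"))
  gm <- map_genes_to_status(list(S1 = seg), genes)
  expect_equal(gm["G1", "S1"], 1L)          # strictly inside a gain
  expect_equal(gm["G3", "S1"], 0L)          # no overlap
  ## G2: ~59% loss (50-55.9 Mb), ~41% gain (56-60 Mb) -> loss, flagged
  expect_equal(gm["G2", "S1"], -1L)
  expect_true(attr(gm, "ambiguous")["G2", "S1"])
  expect_false(attr(gm, "ambiguous")["G1", "S1"])
})

test_that("per-gene scans find planted genes and stay calibrated on nulls", {
  set.seed(71)
  n <- 200
  clin <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     tumor_type = "lactotroph",
                     grade = sample(c("1a", "2a"), n, TRUE),
                     age = rnorm(n, 47, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     recurrence = NA)
  ## planted gene: alteration multiplies odds of recurrence by 8
  alt_planted <- rbinom(n, 1, 0.4)
  clin$recurrence <- rbinom(n, 1, plogis(-1 + log(8) * alt_planted))
  gm <- rbind(PLANTED = as.integer(alt_planted),
              matrix(rbinom(50 * n, 1, 0.3), 50, n,
                     dimnames = list(sprintf("N%02d", 1:50), NULL)))
  colnames(gm) <- clin$sample_id
  gm[2, ] <- 0L                            # constant gene
  res <- per_gene_scan(gm, clin, scope = "lactotroph")
  expect_equal(res$flag[2], "constant")
  expect_lt(res$p_adj_uni[res$gene == "PLANTED"], 0.05)
  expect_lt(res$p_adj_multi[res$gene == "PLANTED"], 0.05)

  ## permuted labels: about 5% of null genes significant raw
  set.seed(72)
  clin2 <- clin
  clin2$recurrence <- sample(clin$recurrence)
  gm2 <- matrix(rbinom(2000 * 60, 1, 0.3), 2000, 60,
                dimnames = list(sprintf("g%04d", 1:2000),
                                clin$sample_id[1:60]))
  res2 <- per_gene_scan(gm2, clin2[1:60, ], scope = "lactotroph")
  frac <- mean(res2$p_uni < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})
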