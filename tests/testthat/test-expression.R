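test_that("differential expression combines signed fold change and t-test", {
  ## gene means built exactly: 10 vs 5, 8 vs 8, 2 vs 9
  jit4 <- c(-0.4, 0.4, -0.2, 0.2)     # zero-sum jitter, exact means
  expr <- rbind(UP2 = c(10 + jit4, 5 + jit4 / 2),
                FLAT = c(8 + jit4, 8 + jit4),
                DOWN = c(2 + jit4 / 4, 9 + jit4))
  groups <- rep(c("recurrent", "non_recurrent"), each = 4)
  de <- differential_expression(expr, groups)
  expect_equal(de$fc[de$gene == "UP2"], 2)       # exact ratio
  expect_true(de$de[de$gene == "UP2"])           # >= 2 is inclusive
  expect_lte(de$p_value[de$gene == "UP2"], 0.05)
  expect_equal(de$fc[de$gene == "FLAT"], 1)
  expect_false(de$de[de$gene == "FLAT"])
  expect_equal(de$fc[de$gene == "DOWN"], -4.5)   # sign-encoded ratio
  expect_true(de$de[de$gene == "DOWN"])

  ## monotone: raising the FC threshold never adds genes
  de_hi <- differential_expression(expr, groups, fc_min = 5)
  expect_true(all(!de_hi$de | de$de))

  ## zero group mean excluded with a reason
  ez <- expr
  ez["UP2", groups == "recurrent"] <- 0
  dez <- differential_expression(ez, groups)
  expect_equal(dez$flag[dez$gene == "UP2"], "zero_mean")
  expect_false(dez$de[dez$gene == "UP2"])

  expect_error(differential_expression(expr[, c(1, 5:8)],
                                       groups[c(1, 5:8)]), ">= 2")
})

test_that("signal-to-noise ranking follows the floored formula", {
  expr <- rbind(A = c(2, 2, 2.5, 1.5, 1, 1, 1.5, 0.5),
                B = c(5, 5, 5, 5, 5, 5, 5, 5),
                C = c(1, 1, 1.5, 0.5, 2, 2, 2.5, 1.5))
  groups <- rep(c("recurrent", "non_recurrent"), each = 4)
  r <- signal_to_noise_ranking(expr, groups)
  s <- sd(c(2, 2, 2.5, 1.5))       # 0.408, above the 0.2|mean| floor
  expect_equal(r$s2n[r$gene == "A"], 1 / (2 * s), tolerance = 1e-9)
  expect_equal(r$s2n[r$gene == "B"], 0)   # constant gene, floored denom
  expect_equal(r$gene, c("A", "B", "C"))  # descending total order
  expect_equal(r$s2n[r$gene == "C"], -r$s2n[r$gene == "A"])

  ## swapped labels negate the metric, reversing the ranking
  sw <- signal_to_noise_ranking(
    expr, ifelse(groups == "recurrent", "non_recurrent", "recurrent"))
  m1 <- setNames(r$s2n, r$gene)
  m2 <- setNames(sw$s2n, sw$gene)
  expect_equal(m2[names(m1)], -m1)
  expect_equal(sw$gene, rev(r$gene))

  expect_error(signal_to_noise_ranking(expr[, c(1, 5:8)],
                                       groups[c(1, 5:8)]), "undefined")
})

test_that("GSEA enrichment scores equal the brute-force running sum", {
  set.seed(500)
  for (rep in 1:25) {
    N <- sample(8:20, 1)
    genes <- sprintf("g%02d", 1:N)
    metric <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(genes, sample(2:5, 1))
    expect_equal(cnvprog:::gsea_es(genes, metric, set),
                 brute_es(genes, metric, set), tolerance = 1e-12)
  }
  ## single top-ranked gene: full hit mass at position 1 -> ES = 1
  genes <- sprintf("g%02d", 1:10)
  metric <- seq(2, 0.2, length.out = 10)
  expect_equal(cnvprog:::gsea_es(genes, metric, "g01"), 1)
})

test_that("preranked GSEA detects planted sets and stays null-calibrated", {
  set.seed(41)
  N <- 200
  genes <- sprintf("g%03d", 1:N)
  metric <- sort(rnorm(N), decreasing = TRUE)
  ranked <- data.frame(gene = genes, s2n = metric)

  sets <- list(TOP = genes[1:15],
               RAND1 = sample(genes, 15), RAND2 = sample(genes, 15),
               TINY = genes[1])
  res <- gsea_preranked(ranked, sets, n_perm = 500, seed = 4)
  expect_gt(res$es[res$set == "TOP"], 0)
  expect_lt(res$p_value[res$set == "TOP"], 0.05)
  expect_equal(res$flag[res$set == "TINY"], "too_small")
  expect_true(all(res$es[!is.na(res$es)] >= -1 &
                    res$es[!is.na(res$es)] <= 1))
  ## determinism under a fixed seed
  res_b <- gsea_preranked(ranked, sets, n_perm = 500, seed = 4)
  expect_identical(res, res_b)

  ## null: random sets on a random ranking, few nominal rejections
  set.seed(42)
  null_sets <- lapply(1:30, function(i) sample(genes, 12))
  names(null_sets) <- sprintf("S%02d", 1:30)
  res0 <- gsea_preranked(ranked, null_sets, n_perm = 300, seed = 5)
  expect_lt(mean(res0$p_value < 0.05), 0.2)
  expect_lte(mean(res0$significant), 0.1)
})

test_that("fgsea agrees with the enrichment score computation", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  N <- 50
  genes <- sprintf("g%02d", 1:N)
  metric <- sort(rnorm(N), decreasing = TRUE)
  for (rep in 1:5) {
    set <- sample(genes, 8)
    ours <- cnvprog:::gsea_es(genes, metric, set)
    ref <- fgsea::calcGseaStat(setNames(metric, genes),
                               selectedStats = which(genes %in% set),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("GMT files round-trip", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tG1\tG2\tG3", "SET_B\tdesc\tG4\tG5"), tmp)
  sets <- read_gmt(tmp)
  expect_equal(sets$SET_A, c("G1", "G2", "G3"))
  expect_equal(sets$SET_B, c("G4", "G5"))
})

test_that("integration keeps only CNV-significant, DE-flagged genes", {
  scan <- data.frame(gene = c("A", "B", "C", "D"),
                     chrom = c(1, 1, 11, 2),
                     n_altered = 5,
                     p_uni = c(0.003, 0.2, 0.001, 0.004),
                     p_adj_uni = c(0.041, 0.6, 0.02, 0.2),
                     p_multi = c(0.003, 0.25, 0.001, 0.004),
                     p_adj_multi = c(0.046, 0.7, 0.03, 0.04),
                     flag = "")
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   fc = c(10.955, 3, 1.5, -2.5),
                   t_stat = 1, p_value = c(0.004, 0.01, 0.01, 0.02),
                   de = c(TRUE, TRUE, FALSE, TRUE), flag = "")
  tab <- integrate_cnv_expression(scan, de)
  expect_setequal(tab$gene, c("A", "D"))      # C fails DE, B fails CNV
  a <- tab[tab$gene == "A", ]
  expect_equal(a$fc, 10.955)
  expect_equal(a$p_adj_multi, 0.046)
  expect_true(a$in_univariate && a$in_multivariate)
  d <- tab[tab$gene == "D", ]
  expect_false(d$in_univariate)               # only multivariate list
  expect_true(d$in_multivariate)
  ## containment in both input significant sets
  expect_true(all(tab$gene %in% de$gene[de$de]))

  ## empty DE table -> empty integration
  expect_equal(nrow(integrate_cnv_expression(scan, de[0, ])), 0)
})
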