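test_that("probe maps cover all autosomes with the requested class mix", {
  g <- hg19_genome()
  pm <- generate_probe_map(g, 99659, snp_fraction = 0, seed = 11)
  expect_equal(nrow(pm), 99659)
  expect_equal(sum(pm$class == "CGH"), 99659)
  expect_equal(sort(unique(pm$chrom)), 1:22)
  expect_false(any(duplicated(pm$probe_id)))
  expect_false(is.unsorted(order(pm$chrom, pm$pos)))
  ## allocation tracks chromosome length
  counts <- table(pm$chrom)
  expect_gt(stats::cor(as.numeric(counts), g$length), 0.99)
  ## positions inside chromosomes
  expect_true(all(pm$pos >= 1 &
                    pm$pos <= g$length[pm$chrom]))

  pm22 <- generate_probe_map(g, 22, 0, seed = 2)
  expect_equal(as.vector(table(pm22$chrom)), rep(1L, 22))

  mixed <- generate_probe_map(g, 5000, snp_fraction = 0.25, seed = 3)
  expect_equal(sum(mixed$class == "SNP"), 1250)

  expect_identical(generate_probe_map(g, 500, 0.1, seed = 9),
                   generate_probe_map(g, 500, 0.1, seed = 9))
  expect_error(generate_probe_map(g, 10), "at least")
  expect_error(generate_probe_map(g, 100, snp_fraction = 1), "snp_fraction")
})

test_that("default cohort reproduces the study composition", {
  g <- hg19_genome()
  pm <- generate_probe_map(g, 1500, 0.2, seed = 1)
  tr <- generate_cohort_truth(cohort_config(), pm, g, seed = 5)
  tab <- table(tr$clinical$tumor_type)
  expect_equal(tab[["gonadotroph"]], 56)
  expect_equal(tab[["immunonegative"]], 11)
  expect_equal(tab[["somatotroph"]], 56)
  expect_equal(tab[["lactotroph"]], 39)
  expect_equal(tab[["corticotroph"]], 33)
  ## covariates complete, recurrence binary
  core <- tr$clinical[, c("tumor_type", "grade", "age", "sex",
                          "size_class", "secretion", "recurrence")]
  expect_false(any(is.na(core)))
  expect_true(all(tr$clinical$recurrence %in% 0:1))
  ## events lie inside their chromosomes
  for (ev in tr$events) if (nrow(ev)) {
    expect_true(all(ev$start >= 1))
    expect_true(all(ev$end <= g$length[ev$chrom]))
    expect_true(all(ev$state %in% c(-1L, 1L)))
  }
  ## determinism
  tr2 <- generate_cohort_truth(cohort_config(), pm, g, seed = 5)
  expect_identical(tr$state_matrix, tr2$state_matrix)
  expect_identical(tr$clinical, tr2$clinical)
  ## invalid config rejected
  expect_error(cohort_config(burden_median = c(
    gonadotroph = 2, immunonegative = 0, somatotroph = 0,
    lactotroph = 0, corticotroph = 0)), "fractions")
})

test_that("lactotroph burden and gain excess are calibrated", {
  g <- hg19_genome()
  pm <- generate_probe_map(g, 1000, 0, seed = 1)
  cfg <- cohort_config(type_counts = c(lactotroph = 500L))
  tr <- generate_cohort_truth(cfg, pm, g, seed = 21)
  med <- median(tr$altered_fraction)
  expect_gt(med, 0.383 - 0.05)
  expect_lt(med, 0.383 + 0.05)
  ## gains outnumber losses at roughly the configured 90:10 balance
  n_gain <- sum(tr$state_matrix == 1L)
  n_loss <- sum(tr$state_matrix == -1L)
  expect_gt(n_gain / (n_gain + n_loss), 0.8)
})

test_that("planted burden-recurrence effect is recoverable, null is flat", {
  g <- hg19_genome()
  pm <- generate_probe_map(g, 800, 0, seed = 1)
  ## null: OR 1.0 per doubling -> slope about 0
  cfg0 <- cohort_config(type_counts = c(lactotroph = 500L),
                        or_per_doubling = 1.0)
  tr0 <- generate_cohort_truth(cfg0, pm, g, seed = 31)
  b0 <- log2(rowSums(tr0$state_matrix != 0L) + 1)
  fit0 <- glm(tr0$clinical$recurrence ~ b0, family = binomial())
  expect_lt(abs(coef(fit0)[["b0"]]), 0.1)
  ## planted OR 1.3, n = 2000 -> multivariate fit recovers it
  cfg1 <- cohort_config(type_counts = c(lactotroph = 2000L))
  tr1 <- generate_cohort_truth(cfg1, pm, g, seed = 32)
  alt_like <- tr1$state_matrix
  summ <- alteration_fractions(alt_like)
  res <- burden_association(summ, tr1$clinical, scope = "lactotroph",
                            adjusted = TRUE)
  expect_gt(res$or, 1.2)
  expect_lt(res$or, 1.4)
})

test_that("log2-ratio forward model has exact dosage means and noise", {
  pm <- grid_probe_map(40, chroms = 1:3)
  ev_gain <- data.frame(chrom = 2, start = 1,
                        end = hg19_genome()$length[2], state = 1L)
  empty <- data.frame(chrom = integer(), start = numeric(),
                      end = numeric(), state = integer())
  tr <- make_truth(list(A = ev_gain, B = empty), pm)

  noiseless <- simulate_l2r_profiles(tr, pm, noise_sd = 0, purity = 1,
                                     seed = 1)
  expect_equal(unname(noiseless["B", ]), rep(0, ncol(noiseless)))
  expect_equal(unname(noiseless["A", pm$chrom == 2]),
               rep(log2(3 / 2), 40))
  expect_equal(unname(noiseless["A", pm$chrom != 2]), rep(0, 80))
  ## reduced purity shrinks the shift
  half <- simulate_l2r_profiles(tr, pm, noise_sd = 0, purity = 0.5,
                                seed = 1)
  expect_equal(unname(half["A", pm$chrom == 2]),
               rep(log2(2.5 / 2), 40))

  ## noise sd recovered within 5% over 10^4 probes
  pm_big <- grid_probe_map(455)
  tr_big <- make_truth(list(A = empty), pm_big)
  x <- simulate_l2r_profiles(tr_big, pm_big, noise_sd = 0.15, seed = 4)
  expect_lt(abs(sd(x[1, ]) - 0.15) / 0.15, 0.05)

  bad <- tr
  bad$events$A$chrom <- 40
  expect_error(simulate_l2r_profiles(bad, pm), "unknown chromosome")
})

test_that("expression simulation is dosage-linked and recovers planted effects", {
  g <- hg19_genome()
  pm <- grid_probe_map(10, chroms = 1:4)
  genes <- generate_gene_annotation(g, 300, seed = 6)
  empty <- data.frame(chrom = integer(), start = numeric(),
                      end = numeric(), state = integer())
  evs <- setNames(rep(list(empty), 32), sprintf("S%03d", 1:32))
  tr <- make_truth(evs, pm)

  ## null: no events, no DE genes -> group fold changes near 1
  expr0 <- simulate_expression(tr, genes, samples = tr$clinical$sample_id,
                               noise_sd = 0.1, seed = 7)
  rec <- tr$clinical$recurrence == 1
  fc0 <- rowMeans(expr0[, rec]) / rowMeans(expr0[, !rec])
  expect_lt(max(abs(log2(fc0))), 0.35)

  ## planted 2-fold effect, low noise -> recovered in [1.8, 2.2]
  de <- genes$gene[1:10]
  expr1 <- simulate_expression(tr, genes, samples = tr$clinical$sample_id,
                               de_genes = de, de_effect = 2,
                               noise_sd = 0.05, seed = 8)
  fc1 <- rowMeans(expr1[de, rec]) / rowMeans(expr1[de, !rec])
  expect_true(all(fc1 > 1.8 & fc1 < 2.2))

  ## dosage monotonicity: gene inside a loss has lower expression
  ev_loss <- data.frame(chrom = genes$chrom[1], start = genes$start[1] - 1,
                        end = genes$end[1] + 1, state = -1L)
  tr2 <- make_truth(list(L = ev_loss, N = empty), pm)
  e2 <- simulate_expression(tr2, genes, samples = c("L", "N"),
                            noise_sd = 0, seed = 9)
  expect_equal(e2[genes$gene[1], "L"] / e2[genes$gene[1], "N"], 0.5)

  expect_error(simulate_expression(tr, genes, de_genes = "NOPE"),
               "unknown gene")
})
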