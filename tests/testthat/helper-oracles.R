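## Independent oracles and fixture builders used across the suite.

## Brute-force step-up FDR adjustment (independent of stats::p.adjust).
brute_step_up <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- ps[i] * m * cm / i
  ## enforce monotonicity from the largest rank down, cap at 1
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Brute-force Ward (ward.D2) agglomeration by the Lance-Williams
## update on a small distance matrix; returns merge heights and the
## partition sizes at k clusters.
lw_ward_merge_heights <- function(D) {
  n <- nrow(D)
  d <- D
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bh <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      i <- active[a]; j <- active[b]
      if (d[i, j] < bh) { bh <- d[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2 <- ((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
               nk * d[i, j]^2) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- sqrt(d2)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

## Brute-force GSEA enrichment score: direct evaluation of the
## weighted running sum at every list position.
brute_es <- function(genes, metric, set, weight = 1) {
  N <- length(genes)
  hit <- genes %in% set
  wsum <- sum(abs(metric[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(metric[i])^weight / wsum else
      -1 / (N - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

## Exhaustive maximal-arc search (oracle for the segmentation core).
brute_max_arc <- function(x, s, min_w) {
  n <- length(x)
  best <- list(stat = -1, i = NA, j = NA)
  for (k in min_w:(n - min_w)) for (i in 0:(n - k)) {
    j <- i + k
    m_in <- mean(x[(i + 1):j])
    m_out <- mean(x[-((i + 1):j)])
    T <- abs(m_in - m_out) / (s * sqrt(1 / k + 1 / (n - k)))
    if (T > best$stat * (1 + 1e-12) + 1e-15)
      best <- list(stat = T, i = i, j = j)
  }
  best
}

## Small uniformly spaced probe map (deterministic, for hand-built
## profiles).
grid_probe_map <- function(n_per_chr, chroms = 1:22,
                           genome = hg19_genome()) {
  pieces <- lapply(chroms, function(ci) {
    L <- genome$length[ci]
    pos <- round(seq(L / (n_per_chr + 1), L * n_per_chr / (n_per_chr + 1),
                     length.out = n_per_chr))
    data.frame(probe_id = sprintf("c%02dp%07d", ci, seq_len(n_per_chr)),
               chrom = ci, pos = pos, class = "CGH")
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("probe_map", "data.frame")
  out
}

## Hand-built truth object around explicit event tables.
make_truth <- function(events_by_sample, probe_map,
                       loh_by_sample = NULL, clinical = NULL,
                       genome = hg19_genome()) {
  ids <- names(events_by_sample)
  n <- length(ids)
  empty_iv <- data.frame(chrom = integer(), start = numeric(),
                         end = numeric())
  if (is.null(loh_by_sample))
    loh_by_sample <- setNames(rep(list(empty_iv), n), ids)
  state <- matrix(0L, n, nrow(probe_map),
                  dimnames = list(ids, probe_map$probe_id))
  for (i in seq_len(n)) {
    ev <- events_by_sample[[i]]
    if (nrow(ev)) for (r in seq_len(nrow(ev))) {
      hit <- probe_map$chrom == ev$chrom[r] &
        probe_map$pos >= ev$start[r] & probe_map$pos <= ev$end[r]
      state[i, hit] <- ev$state[r]
    }
  }
  if (is.null(clinical))
    clinical <- data.frame(sample_id = ids, tumor_type = "lactotroph",
                           grade = "2a", age = 45, sex = "M",
                           size_class = "macro",
                           secretion = "functioning", gnas = NA,
                           usp8 = NA,
                           recurrence = rep_len(c(1L, 0L), n),
                           stringsAsFactors = FALSE)
  out <- list(clinical = clinical, events = events_by_sample,
              loh = loh_by_sample, state_matrix = state,
              altered_fraction = rowMeans(state != 0L),
              genome = genome, config = cohort_config())
  class(out) <- c("cnv_truth", "list")
  out
}

noise_free_config <- function(outdir = NULL, seed = 5) {
  ## burdens capped below half the genome so the copy-neutral level is
  ## identifiable without an external anchor; focal events wide enough
  ## to always cover several probes
  cohort <- cohort_config(
    type_counts = c(gonadotroph = 6L, immunonegative = 2L,
                    somatotroph = 6L, lactotroph = 8L,
                    corticotroph = 4L),
    burden_max = c(gonadotroph = 0.097, immunonegative = 0.165,
                   somatotroph = 0.40, lactotroph = 0.40,
                   corticotroph = 0.40),
    focal_range = c(10e6, 20e6),
    noise_sd = 1e-4)
  pipeline_config(outdir = outdir, seed = seed, n_probes = 4000L,
                  cohort = cohort, n_genes = 300L,
                  scopes = c("cohort", "lactotroph"))
}
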