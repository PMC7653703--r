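#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of a 195-tumor multi-type PitNET aCGH
#' cohort: per-type sample counts, per-type alteration-burden
#' distributions (probability of carrying any CNV, overall-median and
#' maximum altered-probe fraction), per-type gain:loss balance, a
#' three-component event-length mix (whole chromosome / whole arm /
#' focal 1-20 Mb), per-type cnLOH rates, and a logistic recurrence model
#' with grade and age effects plus a lactotroph-specific burden effect
#' expressed as an odds ratio per doubling of altered probes.
#'
#' Burden draws use a scaled Beta(1, b) distribution per type; `b` is
#' solved in closed form so that the type's overall (zeros included)
#' median altered fraction matches `burden_median` given `p_altered`.
#'
#' @param type_counts named integer vector of tumors per type.
#' @param p_altered named vector, probability a tumor carries >= 1 CNV.
#' @param burden_median named vector, target overall median altered
#'   fraction per type (zeros included).
#' @param burden_max named vector, maximum altered fraction per type.
#' @param gain_ratio named vector, probability an event is a gain.
#' @param event_mix probabilities for (whole_chrom, arm, focal) events.
#' @param focal_range focal event length range in base pairs.
#' @param loh_p named vector, probability a tumor carries >= 1 cnLOH.
#' @param recurrence_rate named vector, marginal 5-year recurrence rate
#'   per type.
#' @param grade_probs probabilities of grades 1a/1b/2a/2b.
#' @param or_grade2a,or_grade2b recurrence odds ratios vs grade 1a/1b.
#' @param or_age_10y recurrence odds ratio per 10 additional years.
#' @param or_per_doubling lactotroph recurrence odds ratio per doubling
#'   of altered probe count (the planted prognostic effect).
#' @param age_mean,age_sd age-at-surgery distribution (years).
#' @param p_female probability of female sex.
#' @param noise_sd default log2-ratio noise standard deviation.
#' @param purity default tumor purity (clonal fraction) in (0, 1].
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(
    type_counts = c(gonadotroph = 56L, immunonegative = 11L,
                    somatotroph = 56L, lactotroph = 39L, corticotroph = 33L),
    p_altered = c(gonadotroph = 24 / 56, immunonegative = 2 / 11,
                  somatotroph = 37 / 56, lactotroph = 34 / 39,
                  corticotroph = 24 / 33),
    burden_median = c(gonadotroph = 0, immunonegative = 0,
                      somatotroph = 0.048, lactotroph = 0.383,
                      corticotroph = 0.111),
    burden_max = c(gonadotroph = 0.097, immunonegative = 0.165,
                   somatotroph = 0.998, lactotroph = 0.967,
                   corticotroph = 0.766),
    gain_ratio = c(gonadotroph = 0.70, immunonegative = 0.50,
                   somatotroph = 0.75, lactotroph = 0.90,
                   corticotroph = 0.70),
    event_mix = c(whole_chrom = 0.4, arm = 0.3, focal = 0.3),
    focal_range = c(1e6, 20e6),
    loh_p = c(gonadotroph = 13 / 56, immunonegative = 2 / 11,
              somatotroph = 17 / 56, lactotroph = 15 / 39,
              corticotroph = 9 / 33),
    recurrence_rate = c(gonadotroph = 33 / 56, immunonegative = 5 / 11,
                        somatotroph = 40 / 56, lactotroph = 28 / 39,
                        corticotroph = 18 / 33),
    grade_probs = c(`1a` = 62, `1b` = 9, `2a` = 89, `2b` = 35) / 195,
    or_grade2a = 4.3, or_grade2b = 8.7, or_age_10y = 0.6,
    or_per_doubling = 1.3,
    age_mean = 47.1, age_sd = 14.3, p_female = 0.431,
    noise_sd = 0.15, purity = 1.0) {
  types <- names(type_counts)
  for (nm in c("p_altered", "burden_median", "burden_max", "gain_ratio",
               "loh_p", "recurrence_rate")) {
    v <- get(nm)
    if (!all(types %in% names(v)))
      stop("'", nm, "' must name every tumor type")
  }
  if (any(type_counts < 0)) stop("type counts must be >= 0")
  if (any(burden_median > 1) || any(burden_max > 1))
    stop("burden targets are fractions and must be <= 1")
  probs <- c(p_altered, loh_p, recurrence_rate, grade_probs, event_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(c(or_grade2a, or_grade2b, or_age_10y, or_per_doubling) <= 0))
    stop("odds-ratio parameters must be > 0")
  cfg <- list(
    type_counts = type_counts, p_altered = p_altered,
    burden_median = burden_median, burden_max = burden_max,
    gain_ratio = gain_ratio, event_mix = event_mix,
    focal_range = focal_range, loh_p = loh_p,
    recurrence_rate = recurrence_rate, grade_probs = grade_probs,
    or_grade2a = or_grade2a, or_grade2b = or_grade2b,
    or_age_10y = or_age_10y, or_per_doubling = or_per_doubling,
    age_mean = age_mean, age_sd = age_sd, p_female = p_female,
    noise_sd = noise_sd, purity = purity)
  class(cfg) <- c("cohort_config", "list")
  cfg
}

## Beta(1, b) shape giving quantile q at value m (both on (0,1)):
## qbeta(q, 1, b) = 1 - (1-q)^(1/b) = m  =>  b = log(1-q)/log(1-m)
beta_shape_for_quantile <- function(q, m) log1p(-q) / log1p(-m)

## Conditional burden quantile needed so the overall (zeros included)
## median hits `target` when a fraction `p_alt` of tumors are altered.
conditional_burden_quantile <- function(p_alt, target, max_frac) {
  q <- (0.5 - (1 - p_alt)) / p_alt
  if (q <= 0 || target <= 0) {
    ## overall median is 0 regardless; pick a mild conditional law
    list(q = 0.5, m = 0.15)
  } else {
    list(q = q, m = min(target / max_frac, 0.99))
  }
}

## Draw non-overlapping CNV events on one genome until the covered probe
## fraction reaches `target_frac`.
draw_events <- function(target_frac, genome, probe_map, gain_p, event_mix,
                        focal_range) {
  e_chrom <- integer(0); e_start <- numeric(0)
  e_end <- numeric(0); e_state <- integer(0)
  covered <- vector("list", 22L)
  n_tot <- nrow(probe_map)
  frac <- 0
  tries <- 0L
  probe_chr <- probe_map$chrom
  probe_pos <- probe_map$pos
  kinds <- names(event_mix)
  while (frac < target_frac && tries < 500L) {
    tries <- tries + 1L
    kind <- kinds[sample.int(3L, 1L, prob = event_mix)]
    ci <- sample.int(22L, 1L, prob = genome$length)
    L <- genome$length[ci]
    cen <- genome$centromere[ci]
    if (kind == "whole_chrom") {
      iv <- c(1, L)
    } else if (kind == "arm") {
      iv <- if (runif(1) < 0.5) c(1, floor(cen)) else c(floor(cen) + 1, L)
    } else {
      len <- runif(1, focal_range[1], min(focal_range[2], L - 1))
      st <- floor(runif(1, 1, L - len))
      iv <- c(st, st + len)
    }
    prev <- covered[[ci]]
    if (!is.null(prev) &&
        any(iv[1] <= prev[, 2] & iv[2] >= prev[, 1])) next
    covered[[ci]] <- rbind(prev, iv)
    e_chrom <- c(e_chrom, ci)
    e_start <- c(e_start, iv[1])
    e_end <- c(e_end, iv[2])
    e_state <- c(e_state, if (runif(1) < gain_p) 1L else -1L)
    n_cov <- sum(probe_chr == ci & probe_pos >= iv[1] &
                   probe_pos <= iv[2])
    frac <- frac + n_cov / n_tot
  }
  data.frame(chrom = e_chrom, start = e_start, end = e_end,
             state = e_state)
}

## cnLOH intervals in regions left copy-neutral by `events`.
draw_loh <- function(n_iv, genome, events, span_range = c(10e6, 40e6)) {
  l_chrom <- integer(0); l_start <- numeric(0); l_end <- numeric(0)
  tries <- 0L
  while (length(l_chrom) < n_iv && tries < 200L) {
    tries <- tries + 1L
    ci <- sample.int(22L, 1L, prob = genome$length)
    L <- genome$length[ci]
    len <- runif(1, span_range[1], min(span_range[2], L - 1))
    st <- floor(runif(1, 1, L - len))
    iv <- c(st, st + len)
    hit_ev <- events$chrom == ci & iv[1] <= events$end &
      iv[2] >= events$start
    if (any(hit_ev)) next
    hit_prev <- l_chrom == ci & iv[1] <= l_end & iv[2] >= l_start
    if (any(hit_prev)) next
    l_chrom <- c(l_chrom, ci)
    l_start <- c(l_start, iv[1])
    l_end <- c(l_end, iv[2])
  }
  data.frame(chrom = l_chrom, start = l_start, end = l_end)
}

## Probe states (-1/0/+1) implied by an event table.
events_to_states <- function(events, probe_map) {
  st <- integer(nrow(probe_map))
  if (nrow(events)) for (r in seq_len(nrow(events))) {
    hit <- probe_map$chrom == events$chrom[r] &
      probe_map$pos >= events$start[r] & probe_map$pos <= events$end[r]
    st[hit] <- events$state[r]
  }
  st
}

#' Generate ground-truth CNV/LOH sets and clinical covariates
#'
#' Draws, for each tumor: clinical covariates (type, grade, age, sex,
#' size, secretion, GNAS/USP8 status where applicable), a target
#' altered-probe fraction from the per-type burden law, non-overlapping
#' CNV events realizing that fraction, cnLOH intervals in copy-neutral
#' space, and a 5-year recurrence label from the configured logistic
#' model.  The lactotroph burden effect enters as
#' `log(or_per_doubling)` per unit of `log2(altered probes + 1)`,
#' centered within type so per-type recurrence rates stay near their
#' targets.
#'
#' @param config a [cohort_config()].
#' @param probe_map a probe map from [generate_probe_map()].
#' @param genome the [genome_spec()] the probe map was built on.
#' @param seed integer seed.
#' @return a list of class `cnv_truth` with elements `clinical`
#'   (data.frame), `events` (per-sample list of event tables), `loh`
#'   (per-sample list of interval tables), `state_matrix` (sample x
#'   probe matrix in {-1, 0, +1}), `altered_fraction` (named vector),
#'   and `config`.
#' @export
generate_cohort_truth <- function(config, probe_map, genome = hg19_genome(),
                                  seed = 1L) {
  if (!inherits(config, "cohort_config")) stop("invalid config")
  stopifnot_probe_map(probe_map)
  if (nrow(probe_map) == 0L) stop("probe map is empty")
  set.seed(as.integer(seed))

  types <- rep(names(config$type_counts), config$type_counts)
  n <- length(types)
  ids <- sprintf("S%03d", seq_len(n))
  n_probes <- nrow(probe_map)

  grade <- sample(names(config$grade_probs), n, TRUE, config$grade_probs)
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 15), 90)
  sex <- ifelse(runif(n) < config$p_female, "F", "M")
  size <- sample(c("micro", "macro", "giant"), n, TRUE,
                 prob = c(13, 173, 8) / 194)
  secretion <- ifelse(types %in% c("gonadotroph", "immunonegative"),
                      "silent",
                      ifelse(runif(n) < 0.12, "silent", "functioning"))
  gnas <- ifelse(types == "somatotroph",
                 sample(c("wt", "mutation", NA), n, TRUE,
                        prob = c(40, 13, 3) / 56), NA)
  usp8 <- ifelse(types == "corticotroph",
                 sample(c("wt", "mutation", NA), n, TRUE,
                        prob = c(22, 5, 6) / 33), NA)

  events <- vector("list", n)
  loh <- vector("list", n)
  state_matrix <- matrix(0L, n, n_probes,
                         dimnames = list(ids, probe_map$probe_id))
  target_frac <- numeric(n)
  for (i in seq_len(n)) {
    ty <- types[i]
    if (runif(1) < config$p_altered[ty]) {
      par <- conditional_burden_quantile(config$p_altered[ty],
                                         config$burden_median[ty],
                                         config$burden_max[ty])
      b <- beta_shape_for_quantile(par$q, par$m)
      target_frac[i] <- config$burden_max[ty] *
        (1 - (1 - runif(1))^(1 / b))   # qbeta(u, 1, b) in closed form
      events[[i]] <- draw_events(target_frac[i], genome, probe_map,
                                 config$gain_ratio[ty], config$event_mix,
                                 config$focal_range)
    } else {
      events[[i]] <- draw_events(0, genome, probe_map, 0.5,
                                 config$event_mix, config$focal_range)
    }
    if (runif(1) < config$loh_p[ty])
      loh[[i]] <- draw_loh(sample(1:2, 1L), genome, events[[i]])
    else
      loh[[i]] <- draw_loh(0L, genome, events[[i]])
    state_matrix[i, ] <- events_to_states(events[[i]], probe_map)
  }
  names(events) <- names(loh) <- ids
  altered_frac <- rowMeans(state_matrix != 0L)
  altered_count <- rowSums(state_matrix != 0L)

  ## recurrence model
  b_burden <- log2(altered_count + 1)
  eta <- log(config$or_grade2a) * (grade == "2a") +
    log(config$or_grade2b) * (grade == "2b") +
    log(config$or_age_10y) * (age - config$age_mean) / 10
  is_lac <- types == "lactotroph"
  if (any(is_lac))
    eta[is_lac] <- eta[is_lac] + log(config$or_per_doubling) *
      (b_burden[is_lac] - mean(b_burden[is_lac]))
  for (ty in names(config$type_counts)) {
    sel <- types == ty
    if (!any(sel)) next
    ## intercept solving mean(plogis(eta + c)) = target recurrence rate
    target <- config$recurrence_rate[ty]
    cc <- stats::uniroot(function(c0) mean(plogis(eta[sel] + c0)) - target,
                         c(-20, 20))$root
    eta[sel] <- eta[sel] + cc
  }
  recurrence <- rbinom(n, 1L, plogis(eta))

  clinical <- data.frame(
    sample_id = ids, tumor_type = types, grade = grade, age = age,
    sex = sex, size_class = size, secretion = secretion,
    gnas = gnas, usp8 = usp8, recurrence = recurrence,
    stringsAsFactors = FALSE)
  out <- list(clinical = clinical, events = events, loh = loh,
              state_matrix = state_matrix,
              altered_fraction = setNames(altered_frac, ids),
              genome = genome, config = config)
  class(out) <- c("cnv_truth", "list")
  out
}
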