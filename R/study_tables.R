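#' Printed summary tables of the motivating PitNET cohort study
#'
#' The package ships the published count tables of the 195-tumor
#' multicentric PitNET aCGH cohort it is modeled on: the clinical
#' composition by recurrence status, the altered / non-altered tumor
#' counts per type, and the whole-chromosome / arm event counts.  They
#' serve as worked-example inputs: every proportion the study prints
#' can be recomputed from them with [study_proportions()].
#'
#' @param which `"cohort"`, `"altered"`, or `"large_events"`.
#' @return the corresponding count data.frame.
#' @export
study_counts <- function(which = c("cohort", "altered",
                                   "large_events")) {
  which <- match.arg(which)
  f <- switch(which,
              cohort = "study_cohort_counts.tsv",
              altered = "study_altered_counts.tsv",
              large_events = "study_large_event_counts.tsv")
  path <- system.file("extdata", f, package = "cnvprog")
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Recompute the study's printed proportions from its count tables
#'
#' Exact percentage recomputation from [study_counts()]: cohort-level
#' shares (per tumor type, recurrence rate), per-type altered-tumor
#' rates, mutation rates among assessable tumors, and the frequency of
#' the most common whole-chromosome gain.
#'
#' @return data.frame `quantity`, `numerator`, `denominator`, `pct`.
#' @export
study_proportions <- function() {
  co <- study_counts("cohort")
  al <- study_counts("altered")
  le <- study_counts("large_events")
  tot <- co[co$variable == "n", ]
  n_all <- tot$recurrence + tot$no_recurrence
  row <- function(quantity, num, den)
    data.frame(quantity = quantity, numerator = num, denominator = den,
               pct = 100 * num / den)
  ty <- co[co$variable == "tumor_type", ]
  out <- list(row("recurrence_rate", tot$recurrence, n_all))
  for (i in seq_len(nrow(ty)))
    out[[length(out) + 1L]] <- row(
      paste0(ty$level[i], "_share"),
      ty$recurrence[i] + ty$no_recurrence[i], n_all)
  for (i in seq_len(nrow(al)))
    out[[length(out) + 1L]] <- row(
      paste0(al$tumor_type[i], "_altered_rate"), al$altered[i],
      al$altered[i] + al$not_altered[i])
  gn <- co[co$variable == "gnas", ]
  out[[length(out) + 1L]] <- row(
    "gnas_mutation_rate", sum(gn$recurrence[gn$level == "mutation"],
                              gn$no_recurrence[gn$level == "mutation"]),
    sum(gn$recurrence, gn$no_recurrence))
  us <- co[co$variable == "usp8", ]
  out[[length(out) + 1L]] <- row(
    "usp8_mutation_rate", sum(us$recurrence[us$level == "mutation"],
                              us$no_recurrence[us$level == "mutation"]),
    sum(us$recurrence, us$no_recurrence))
  top <- le[le$scope == "chromosome" & le$direction == "gain", ]
  top <- top[which.max(top$n_patients), ]
  out[[length(out) + 1L]] <- row(
    sprintf("whole_chr%d_gain_rate", top$chrom), top$n_patients,
    top$n_total)
  do.call(rbind, out)
}
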