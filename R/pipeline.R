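#' Pipeline configuration
#'
#' One object drives the full synthetic-cohort analysis: generation
#' parameters, per-stage statistical parameters, stage toggles, and the
#' master seed every stage-specific seed is derived from.
#'
#' @param outdir output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @param seed master integer seed.
#' @param n_probes probe count of the simulated array.
#' @param snp_fraction fraction of SNP-class probes.
#' @param cohort a [cohort_config()].
#' @param seg a [seg_config()].
#' @param dlrs_exclude,dlrs_loh QC thresholds.
#' @param cluster_k number of clusters.
#' @param n_genes genes in the synthetic annotation.
#' @param scopes tumor types (plus `"cohort"`) for burden
#'   associations.
#' @param probe_scan_scope scope for the per-probe scan (`NULL` skips
#'   it).
#' @param gene_scan_scope scope for the per-gene scan and expression
#'   integration (`NULL` skips them).
#' @param stages character vector of stages to run, in pipeline order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = NULL, seed = 1L, n_probes = 10000L,
                            snp_fraction = 0.2,
                            cohort = cohort_config(),
                            seg = seg_config(),
                            dlrs_exclude = 0.47, dlrs_loh = 0.3,
                            cluster_k = 3L, n_genes = 1500L,
                            scopes = c("cohort", "lactotroph",
                                       "corticotroph", "somatotroph"),
                            probe_scan_scope = "lactotroph",
                            gene_scan_scope = "lactotroph",
                            stages = c("simulate", "preprocess",
                                       "segment", "instability",
                                       "cluster", "prognosis",
                                       "integrate")) {
  order_all <- c("simulate", "preprocess", "segment", "instability",
                 "cluster", "prognosis", "integrate")
  stages <- intersect(order_all, stages)
  ## every stage needs all earlier stages
  need <- order_all[seq_len(max(match(stages, order_all)))]
  if (!all(need %in% stages))
    stop("stage toggles leave dependent stages unrunnable; missing: ",
         paste(setdiff(need, stages), collapse = ", "))
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              n_probes = as.integer(n_probes),
              snp_fraction = snp_fraction, cohort = cohort, seg = seg,
              dlrs_exclude = dlrs_exclude, dlrs_loh = dlrs_loh,
              cluster_k = as.integer(cluster_k),
              n_genes = as.integer(n_genes), scopes = scopes,
              probe_scan_scope = probe_scan_scope,
              gene_scan_scope = gene_scan_scope, stages = stages)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

## Stable hash of the configuration (md5 of its canonical JSON).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages in order: simulate (probe map, cohort truth, log2-ratio and
#' homozygosity matrices) -> preprocess (normalization, DLRS QC) ->
#' segment (CBS, centralization, state calls, alteration and cnLOH
#' matrices) -> instability (fractions, large events, per-type
#' summaries) -> cluster (Jaccard/Ward, clinical associations) ->
#' prognosis (burden associations per scope, per-probe scan, gene
#' mapping, per-gene scan) -> integrate (expression simulation, DE,
#' ranking, GSEA, CNV-expression intersection).  Reruns with the same
#' configuration are bit-identical.  When `config$outdir` is set,
#' stage outputs are written there as TSV.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` list; its `data` element holds the full
#'   in-memory objects, the remaining elements are JSON-serializable
#'   summaries.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("invalid config")
  out <- list()
  dir_out <- config$outdir
  if (!is.null(dir_out) && !dir.exists(dir_out))
    dir.create(dir_out, recursive = TRUE)
  emit <- function(fn, name) if (!is.null(dir_out))
    fn(file.path(dir_out, name))
  stage <- function(name) name %in% config$stages

  ## --- simulate -----------------------------------------------------
  genome <- hg19_genome()
  probe_map <- generate_probe_map(genome, config$n_probes,
                                  config$snp_fraction,
                                  seed = config$seed)
  truth <- generate_cohort_truth(config$cohort, probe_map, genome,
                                 seed = config$seed + 1L)
  l2r <- simulate_l2r_profiles(truth, probe_map,
                               seed = config$seed + 2L)
  hom <- simulate_snp_homozygosity(truth, probe_map,
                                   seed = config$seed + 3L)
  emit(function(p) write_probe_map(probe_map, p), "probe_map.tsv")
  emit(function(p) write_clinical(truth$clinical, p), "clinical.tsv")
  emit(function(p) write_truth_json(truth, p), "truth.json")
  emit(function(p) write_matrix_tsv(l2r, p, transpose = TRUE,
                                    id_col = "probe_id"), "l2r.tsv")

  ## --- preprocess ---------------------------------------------------
  norm <- qc <- part <- NULL
  kept <- character(0)
  if (stage("preprocess")) {
    norm <- normalize_profiles(l2r)
    qc <- qc_metrics(norm, probe_map, config$dlrs_exclude,
                     config$dlrs_loh)
    part <- apply_qc(qc, config$dlrs_exclude)
    kept <- part$kept$sample_id
    emit(function(p) data.table::fwrite(qc, p, sep = "\t"), "qc.tsv")
  }

  ## --- segment ------------------------------------------------------
  seg_sets <- list()
  alt <- loh_mat <- NULL
  if (stage("segment")) for (s in kept) {
    seg <- cbs_segment(norm[s, ], probe_map, config$seg)
    cen <- centralize_profile(norm[s, ], seg,
                              gain_thr = config$seg$gain_thr,
                              loss_thr = config$seg$loss_thr)
    norm[s, ] <- cen$profile
    seg_sets[[s]] <- call_segment_states(cen$segments, config$seg)
  }
  if (stage("segment") && length(seg_sets)) {
    alt <- build_alteration_matrix(seg_sets, probe_map)
    loh_calls <- list()
    dlrs_by <- setNames(qc$dlrs, qc$sample_id)
    for (s in kept)
      loh_calls[[s]] <- call_cnloh(hom[s, ], alt[s, ], probe_map,
                                   dlrs_by[[s]],
                                   dlrs_loh = config$dlrs_loh)
    loh_mat <- build_loh_matrix(loh_calls, probe_map)
    emit(function(p) write_segments(seg_sets, p), "segments.tsv")
    emit(function(p) write_matrix_tsv(alt, p, transpose = TRUE,
                                      id_col = "probe_id"),
         "alteration_matrix.tsv")
  }

  ## --- instability --------------------------------------------------
  clin_kept <- truth$clinical[truth$clinical$sample_id %in% kept, ]
  summ <- large <- NULL
  med_by_type <- numeric(0)
  if (stage("instability") && !is.null(alt) && nrow(alt)) {
    summ <- alteration_fractions(alt, loh_mat)
    large <- summarize_large_events(alt, probe_map, genome)
    med_by_type <- vapply(split(
      summ$altered_frac,
      clin_kept$tumor_type[match(summ$sample_id,
                                 clin_kept$sample_id)]),
      median, numeric(1))
    emit(function(p) data.table::fwrite(summ, p, sep = "\t"),
         "instability.tsv")
    emit(function(p) data.table::fwrite(large, p, sep = "\t"),
         "large_events.tsv")
  }

  ## --- cluster ------------------------------------------------------
  clusters <- assoc <- NULL
  if (stage("cluster") && !is.null(alt) &&
      nrow(alt) >= config$cluster_k) {
    D <- jaccard_distances(alt)
    clusters <- ward_cut(D, config$cluster_k)
    assoc <- cluster_clinical_association(
      clusters, clin_kept,
      variables = c("tumor_type", "grade", "sex", "size_class",
                    "secretion", "age", "recurrence"),
      seed = config$seed + 4L)
    emit(function(p) data.table::fwrite(
      data.frame(sample_id = names(clusters$assignment),
                 cluster = clusters$assignment), p, sep = "\t"),
      "clusters.tsv")
  }

  ## --- prognosis ----------------------------------------------------
  burden <- NULL
  probe_scan <- gene_scan <- NULL
  genes <- NULL
  if (stage("prognosis") && !is.null(summ)) {
    rows <- lapply(config$scopes, function(sc) {
      tryCatch(burden_association(summ, clin_kept, scope = sc),
               error = function(e)
                 data.frame(predictor = "log2_altered_probes",
                            scope = sc, or = NA, ci_lo = NA, ci_hi = NA,
                            lrt_stat = NA, df = NA, p_value = NA,
                            n = NA, flag = conditionMessage(e)))
    })
    burden <- do.call(rbind, rows)
    if (!is.null(config$probe_scan_scope))
      probe_scan <- per_probe_scan(alt, clin_kept,
                                   scope = config$probe_scan_scope)
    genes <- generate_gene_annotation(genome, config$n_genes,
                                      seed = config$seed + 5L)
    gm <- map_genes_to_status(seg_sets, genes)
    if (!is.null(config$gene_scan_scope))
      gene_scan <- per_gene_scan(gm, clin_kept,
                                 scope = config$gene_scan_scope)
    emit(function(p) data.table::fwrite(burden, p, sep = "\t"),
         "burden_associations.tsv")
    if (!is.null(probe_scan))
      emit(function(p) data.table::fwrite(probe_scan, p, sep = "\t"),
           "per_probe_scan.tsv")
    if (!is.null(gene_scan))
      emit(function(p) data.table::fwrite(gene_scan, p, sep = "\t"),
           "per_gene_scan.tsv")
  }

  ## --- integrate ----------------------------------------------------
  de <- gsea <- integration <- NULL
  if (stage("integrate") && !is.null(config$gene_scan_scope) &&
      !is.null(gene_scan)) {
    sc <- config$gene_scan_scope
    ids <- clin_kept$sample_id[clin_kept$tumor_type == sc]
    rec <- clin_kept$recurrence[match(ids, clin_kept$sample_id)]
    if (length(ids) >= 4 && length(unique(rec)) == 2 &&
        min(table(rec)) >= 2) {
      ## plant recurrence-linked expression on the genes most
      ## associated with recurrence in the CNV scan, so the
      ## integration stage has dosage-plus-expression signal
      ok <- !is.na(gene_scan$p_adj_multi)
      de_genes <- head(gene_scan$gene[ok][
        order(gene_scan$p_adj_multi[ok])], 25L)
      expr <- simulate_expression(truth, genes, samples = ids,
                                  de_genes = de_genes, de_effect = 3,
                                  seed = config$seed + 6L)
      grp <- ifelse(rec == 1, "recurrent", "non_recurrent")
      de <- differential_expression(expr, grp)
      ranked <- signal_to_noise_ranking(expr, grp)
      sets <- lapply(1:10, function(k)
        genes$gene[(1 + (k - 1) * 25):(k * 25)])
      names(sets) <- sprintf("SET_%02d", 1:10)
      gsea <- gsea_preranked(ranked, sets, n_perm = 200L,
                             seed = config$seed + 7L)
      integration <- integrate_cnv_expression(gene_scan, de)
      emit(function(p) data.table::fwrite(de, p, sep = "\t"), "de.tsv")
      emit(function(p) data.table::fwrite(integration, p, sep = "\t"),
           "integration.tsv")
    }
  }

  bundle <- list(
    meta = list(package = "cnvprog",
                version = as.character(packageVersion("cnvprog")),
                seed = config$seed, config_hash = config_hash(config),
                n_probes = config$n_probes,
                n_samples = nrow(truth$clinical)),
    qc = if (!is.null(qc))
      list(n_input = nrow(qc), n_kept = length(kept),
           n_excluded = nrow(part$excluded)) else NULL,
    instability = if (!is.null(summ))
      list(median_altered_frac_by_type = as.list(med_by_type),
           n_large_events = nrow(large)) else NULL,
    clusters = if (!is.null(clusters))
      list(k = clusters$k,
           sizes = as.list(table(clusters$assignment))) else NULL,
    burden_associations = burden,
    probe_scan = if (!is.null(probe_scan))
      list(n_tested = sum(!is.na(probe_scan$p_value)),
           min_p_adj = suppressWarnings(
             min(probe_scan$p_adj, na.rm = TRUE))) else NULL,
    gene_scan = if (!is.null(gene_scan))
      list(n_tested = sum(!is.na(gene_scan$p_uni)),
           n_sig_uni = sum(gene_scan$p_adj_uni < 0.05, na.rm = TRUE),
           n_sig_multi = sum(gene_scan$p_adj_multi < 0.05,
                             na.rm = TRUE)) else NULL,
    integration = if (!is.null(integration))
      list(n_genes = nrow(integration)) else NULL)
  bundle$data <- list(probe_map = probe_map, truth = truth, l2r = l2r,
                      norm = norm, qc = qc, segments = seg_sets,
                      alteration_matrix = alt, loh_matrix = loh_mat,
                      summaries = summ, large_events = large,
                      clusters = clusters, cluster_assoc = assoc,
                      probe_scan = probe_scan, gene_scan = gene_scan,
                      genes = genes, de = de, gsea = gsea,
                      integration = integration,
                      clinical_kept = clin_kept)
  class(bundle) <- c("report_bundle", "list")
  bundle
}

#' Write a machine-readable pipeline report
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param path output path for the JSON report (its directory also
#'   receives TSV summaries when `format = "tsv-dir"`).
#' @param format `"json"` or `"tsv-dir"`.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(bundle, path, format = c("json", "tsv-dir")) {
  format <- match.arg(format)
  if (!inherits(bundle, "report_bundle")) stop("invalid bundle")
  payload <- bundle[setdiff(names(bundle), "data")]
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  if (format == "tsv-dir" && !is.null(bundle$burden_associations))
    data.table::fwrite(bundle$burden_associations,
                       file.path(dirname(path),
                                 "burden_associations.tsv"), sep = "\t")
  invisible(path)
}

#' Reload a JSON pipeline report
#' @param path report path written by [write_report()].
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
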