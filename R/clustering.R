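#' Jaccard distances between alteration profiles
#'
#' For samples A and B, `d = 1 - |A i B| / |A u B|` over probes altered
#' in either sample.  With `encoding = "binary"` (default) a probe is
#' "altered" regardless of direction; with `"three_state"` a probe
#' counts as shared only when both samples carry the same direction
#' (the union is still any-alteration).  Two fully quiet samples are at
#' distance 0 by convention, so alteration-free tumors co-cluster.
#'
#' @param matrix alteration matrix (samples x probes, -1/0/+1).
#' @param encoding `"binary"` or `"three_state"`.
#' @return symmetric numeric matrix of distances in `[0, 1]` with zero
#'   diagonal.
#' @export
jaccard_distances <- function(matrix, encoding = c("binary",
                                                   "three_state")) {
  encoding <- match.arg(encoding)
  A <- matrix != 0L
  sizes <- rowSums(A)
  un <- outer(sizes, sizes, "+") - tcrossprod(A)
  inter <- if (encoding == "binary") tcrossprod(A) else
    tcrossprod(matrix == 1L) + tcrossprod(matrix == -1L)
  d <- 1 - inter / un
  d[un == 0] <- 0            # both profiles quiet
  diag(d) <- 0
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' Ward clustering of a distance matrix, cut at k
#'
#' Agglomerative hierarchy under the squared-distance Ward update
#' (`hclust` method `"ward.D2"`), cut into `k` clusters.  Cluster
#' labels follow `stats::cutree` (order of appearance in the data).
#'
#' @param distances symmetric distance matrix (e.g. from
#'   [jaccard_distances()]).
#' @param k number of clusters (default 3).
#' @return list of class `cnv_clusters`: `assignment` (named integer
#'   vector), `k`, `hclust` (the full linkage object, merge heights
#'   non-decreasing).
#' @export
ward_cut <- function(distances, k = 3L) {
  n <- nrow(distances)
  if (k > n) stop("invalid config: k exceeds the number of samples")
  hc <- hclust(as.dist(distances), method = "ward.D2")
  out <- list(assignment = cutree(hc, k = k), k = as.integer(k),
              hclust = hc)
  class(out) <- c("cnv_clusters", "list")
  out
}

#' Associate clusters with clinical variables
#'
#' Categorical variables: Fisher's exact test (fully exact for small
#' tables; Monte-Carlo with a fixed seed for larger r x c tables, the
#' method used is recorded).  Numeric variables: Kruskal-Wallis.
#' Variables constant across all samples are flagged not testable.
#'
#' @param clusters a `cnv_clusters` (or a named cluster-label vector).
#' @param clinical clinical table with a `sample_id` column.
#' @param variables columns of `clinical` to test (default: all except
#'   `sample_id`).
#' @param mc_cells exact-enumeration size cap: tables with more cells
#'   use Monte-Carlo Fisher p-values.
#' @param B Monte-Carlo replicates.
#' @param seed Monte-Carlo seed.
#' @return data.frame `variable`, `test`, `p_value`, `method`.
#' @export
cluster_clinical_association <- function(clusters, clinical,
                                         variables = NULL,
                                         mc_cells = 12L, B = 1e5,
                                         seed = 1L) {
  labels <- if (inherits(clusters, "cnv_clusters")) clusters$assignment
            else clusters
  if (!all(names(labels) %in% clinical$sample_id))
    stop("clusters and clinical table are not aligned")
  cl <- clinical[match(names(labels), clinical$sample_id), ]
  if (is.null(variables))
    variables <- setdiff(names(clinical), "sample_id")
  rows <- lapply(variables, function(v) {
    x <- cl[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L)
      return(data.frame(variable = v, test = NA_character_,
                        p_value = NA_real_, method = "not_testable"))
    if (is.numeric(x)) {
      kt <- suppressWarnings(kruskal.test(x[ok], factor(labels[ok])))
      data.frame(variable = v, test = "kruskal", p_value = kt$p.value,
                 method = "kruskal-chisq")
    } else {
      tab <- table(x[ok], labels[ok])
      if (length(tab) <= mc_cells) {
        ft <- fisher.test(tab, workspace = 2e7)
        data.frame(variable = v, test = "fisher", p_value = ft$p.value,
                   method = "fisher-exact")
      } else {
        set.seed(as.integer(seed))
        ft <- fisher.test(tab, simulate.p.value = TRUE, B = B)
        data.frame(variable = v, test = "fisher", p_value = ft$p.value,
                   method = sprintf("fisher-montecarlo-B%g", B))
      }
    }
  })
  do.call(rbind, rows)
}
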