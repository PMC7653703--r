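#' Write / read a numeric matrix as TSV
#'
#' On disk the matrix is stored features-by-samples with a header row
#' of sample ids and a leading feature-id column, the layout shared by
#' the log2-ratio and expression tables.  In memory log2-ratio
#' matrices are samples x probes, so use `transpose = TRUE` for them.
#'
#' @param mat numeric matrix.
#' @param path file path.
#' @param transpose write/read the transpose (samples-in-rows
#'   matrices).
#' @param id_col name of the feature-id column.
#' @export
write_matrix_tsv <- function(mat, path, transpose = FALSE,
                             id_col = "feature") {
  m <- if (transpose) t(mat) else mat
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, transpose = FALSE) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1])
  rownames(m) <- ids
  if (transpose) t(m) else m
}

#' Write / read the clinical table as TSV
#' @param clinical data.frame.
#' @param path file path.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t")
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  na.strings = c("NA", "")))
}

#' Write a segment table as TSV
#'
#' Coordinates are 1-based, inclusive at both ends.
#'
#' @param segment_sets named list of per-sample segment tables.
#' @param path file path.
#' @export
write_segments <- function(segment_sets, path) {
  rows <- lapply(names(segment_sets), function(s)
    cbind(sample_id = s, segment_sets[[s]]))
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Write a truth set as JSON
#' @param truth a `cnv_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(clinical = truth$clinical,
                  events = truth$events, loh = truth$loh,
                  altered_fraction = as.list(truth$altered_fraction))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
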