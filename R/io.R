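# Reading the standard on-disk inputs: dense delimited count/intensity
# matrices (samples in rows or columns), sparse MatrixMarket triplets with
# sidecar id files, and phenotype tables.

#' Read a sample-by-feature matrix from delimited text or MatrixMarket
#'
#' Dense CSV/TSV files are read with the first column as identifiers.
#' `.mtx` files are read with [Matrix::readMM()] and require sidecar id
#' files (`row_ids`, `col_ids`: one id per line) naming the matrix rows and
#' columns. Feature ids are treated as opaque strings.
#'
#' @param path file path (`.csv`, `.tsv`/`.txt`, or `.mtx`).
#' @param samples_in `"rows"` (default) or `"columns"`; with `"columns"`
#'   the matrix is transposed after reading so samples are always in rows on
#'   return.
#' @param row_ids,col_ids sidecar id files for `.mtx` input (defaults:
#'   `<path>.rownames` / `<path>.colnames`).
#' @return dense numeric matrix, samples in rows.
#' @export
read_matrix <- function(path, samples_in = c("rows", "columns"),
                        row_ids = NULL, col_ids = NULL) {
  samples_in <- match.arg(samples_in)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(row_ids)) row_ids <- paste0(path, ".rownames")
    if (is.null(col_ids)) col_ids <- paste0(path, ".colnames")
    for (f in c(row_ids, col_ids))
      if (!file.exists(f)) stop(sprintf("sidecar id file not found: %s", f))
    rownames(m) <- readLines(row_ids)
    colnames(m) <- readLines(col_ids)
  } else {
    dt <- data.table::fread(path, header = TRUE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- ids
  }
  if (samples_in == "columns") m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Write a sample-by-feature matrix as TSV
#'
#' @param x matrix with sample rownames.
#' @param path output path.
#' @param id_col name of the identifier column (default `sample_id`).
#' @export
write_matrix <- function(x, path, id_col = "sample_id") {
  dt <- data.table::as.data.table(x, keep.rownames = id_col)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a phenotype table
#'
#' A delimited table whose first column holds sample identifiers, with one
#' outcome column and an optional weight column.
#'
#' @param path TSV/CSV file path.
#' @param outcome_col name of the outcome column.
#' @param weight_col optional name of a weight column.
#' @return data frame with columns `sample_id`, `outcome` and (if
#'   requested) `weight`.
#' @export
read_phenotype <- function(path, outcome_col, weight_col = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE)
  if (!outcome_col %in% names(dt))
    stop(sprintf("phenotype file has no column named '%s' (columns: %s)",
                 outcome_col, paste(names(dt), collapse = ", ")))
  out <- data.frame(sample_id = as.character(dt[[1]]),
                    outcome = dt[[outcome_col]])
  if (!is.null(weight_col)) {
    if (!weight_col %in% names(dt))
      stop(sprintf("phenotype file has no column named '%s'", weight_col))
    out$weight <- as.numeric(dt[[weight_col]])
  }
  out
}
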