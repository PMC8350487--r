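# Plain-text readers/writers for the tabular formats the pipeline
# exchanges: node time series and square matrices as TSV with node ids,
# regional maps and gene tables as two-column / labelled TSV.

#' Read a node time-series matrix from TSV
#'
#' First row holds node ids; subsequent rows are timepoints.
#'
#' @param path TSV path.
#' @return Numeric matrix, timepoints x nodes.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(df)
}

#' Write a node time-series matrix to TSV
#' @param ts Timepoints x nodes matrix with node column names.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix (TSV with ids as header and first column)
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a square matrix to TSV with ids as header and first column
#' @param m Matrix.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a named regional map from a two-column TSV (region, value)
#' @param path TSV path.
#' @return Named numeric vector.
#' @export
read_regional_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a named regional map to a two-column TSV
#' @param map Named numeric vector.
#' @param path Output path.
#' @export
write_regional_map <- function(map, path) {
  utils::write.table(data.frame(region = names(map), value = as.numeric(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
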