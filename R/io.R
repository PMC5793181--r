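# Plain-TSV helpers shared by the pipeline writers.

#' Write a data.frame as TSV (no quoting, no row names)
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Write a feature x sample matrix as TSV with a `feature_id` first column
#' @param matrix numeric matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(feature_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#' @param path input path.
#' @return numeric matrix with feature ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
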