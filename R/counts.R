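# Count matrix container: a plain integer matrix (genes x subjects) with
# unique row and column names, validated at package entry points.

#' Construct a validated gene-by-subject count matrix
#'
#' @param values non-negative integer matrix, genes in rows, subjects in
#'   columns.
#' @param gene_ids,subject_ids identifiers; default taken from `dimnames`.
#' @return the matrix with validated unique dimnames, class `count_matrix`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         subject_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(subject_ids)) {
    stop("count matrix requires gene and subject identifiers")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(subject_ids)) stop("duplicate subject identifiers")
  if (any(values < 0)) stop("counts must be non-negative")
  if (any(values != round(values))) stop("counts must be integral")
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(gene_ids), as.character(subject_ids))
  class(values) <- c("count_matrix", class(matrix()))
  values
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d subjects\n", nrow(x), ncol(x)))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x)
}

#' Read a count matrix from TSV (genes x subjects, header row of subjects)
#' @param path TSV file, first column gene identifiers.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m)
}

#' Write a count matrix as TSV
#' @param counts a [count_matrix()].
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from MatrixMarket with row/column name sidecars
#'
#' Expects `<stem>.mtx`, `<stem>_rownames.txt`, `<stem>_colnames.txt`.
#' @param stem path stem (without `.mtx`).
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, "_rownames.txt"))
  colnames(m) <- readLines(paste0(stem, "_colnames.txt"))
  count_matrix(m)
}

#' Write a count matrix as MatrixMarket with name sidecars
#' @inheritParams write_counts_tsv
#' @param stem path stem (without `.mtx`).
#' @export
write_counts_mtx <- function(counts, stem) {
  Matrix::writeMM(Matrix::Matrix(unclass(counts), sparse = TRUE), paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, "_rownames.txt"))
  writeLines(colnames(counts), paste0(stem, "_colnames.txt"))
  invisible(stem)
}
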