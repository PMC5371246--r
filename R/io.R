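# Tag-table input/output and the logTPM transform.
#
# A tag matrix is an ordinary numeric matrix of non-negative integer counts
# with features as rows and cells as columns; dimnames carry the feature and
# cell identifiers. All downstream functions keep this orientation.

#' Validate a tag matrix
#'
#' Checks that `counts` is a non-negative numeric matrix with unique row
#' (feature) and column (cell) identifiers, generating identifiers where
#' absent.
#'
#' @param counts Numeric matrix, features x cells.
#' @return The validated matrix with complete dimnames.
#' @export
as_tag_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (features x cells)")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("feature identifiers must be unique")
  if (anyDuplicated(colnames(counts))) stop("cell identifiers must be unique")
  counts
}

#' Read a tag table from delimited text
#'
#' Reads a rectangular features x cells table of raw counts. By default the
#' first row holds cell identifiers and the first column feature identifiers.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator (default tab).
#' @param has_header Logical; first row is a header of cell identifiers.
#' @param has_rownames Logical; first column holds feature identifiers.
#' @param transpose Logical; set `TRUE` when the file stores cells as rows.
#' @return A validated tag matrix (features x cells).
#' @export
read_tag_table <- function(path, delimiter = "\t", has_header = TRUE,
                           has_rownames = TRUE, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = has_header,
                      row.names = if (has_rownames) 1L else NULL,
                      check.names = FALSE, comment.char = "",
                      colClasses = NA),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty tag table: ", path)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  as_tag_matrix(m)
}

#' Write a tag table as delimited text
#'
#' @param m Tag matrix.
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_tag_table <- function(m, path, delimiter = "\t") {
  m <- as_tag_matrix(m)
  utils::write.table(m, path, sep = delimiter, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read a tag table in MatrixMarket form
#'
#' Reads a sparse counts matrix plus optional plain-text identifier files
#' (one identifier per line, features then cells).
#'
#' @param mtx_path Path to the MatrixMarket file (features x cells).
#' @param features_path,cells_path Optional identifier files.
#' @return A dense validated tag matrix.
#' @export
read_mtx_tags <- function(mtx_path, features_path = NULL, cells_path = NULL) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  if (!is.null(features_path)) rownames(m) <- readLines(features_path)
  if (!is.null(cells_path)) colnames(m) <- readLines(cells_path)
  as_tag_matrix(m)
}

#' Filter out small libraries
#'
#' Removes cells whose library size (column sum) is below
#' `min_library_size`; cells at exactly the threshold are kept. The default
#' of 10,000 tags is the quality filter used for the biological data sets.
#'
#' @param m Tag matrix.
#' @param min_library_size Minimum total tag count per retained cell.
#' @return Tag matrix restricted to the retained cells.
#' @export
filter_libraries <- function(m, min_library_size = 10000) {
  m <- as_tag_matrix(m)
  keep <- colSums(m) >= min_library_size
  if (!any(keep))
    stop("all cells have library size below ", min_library_size,
         "; lower min_library_size")
  m[, keep, drop = FALSE]
}

#' Drop near-silent features
#'
#' Optional preprocessing: removes features whose total tag count is at or
#' below `max_tag_sum`. Not part of the default pipeline.
#'
#' @param m Tag matrix.
#' @param max_tag_sum Features with total counts <= this value are dropped.
#' @export
filter_features <- function(m, max_tag_sum = 10) {
  m <- as_tag_matrix(m)
  m[rowSums(m) > max_tag_sum, , drop = FALSE]
}

#' Log-transformed tags per million
#'
#' Scales each cell to tags per million and applies
#' `log_base(tpm + pseudocount)`. With the default pseudocount of 1, zero
#' counts map exactly to 0 on the transformed scale.
#'
#' @param m Tag matrix; every cell must have a positive library size.
#' @param base Logarithm base (default 2).
#' @param pseudocount Added before taking logs (default 1).
#' @return Numeric matrix of log-TPM values with attributes `base` and
#'   `pseudocount`, class `"log_tpm"`.
#' @export
log_tpm <- function(m, base = 2, pseudocount = 1) {
  m <- as_tag_matrix(m)
  libsize <- colSums(m)
  if (any(libsize <= 0))
    stop("zero library size in cell(s): ",
         paste(colnames(m)[libsize <= 0], collapse = ", "))
  tpm <- sweep(m, 2L, libsize, "/") * 1e6
  out <- log(tpm + pseudocount, base = base)
  attr(out, "base") <- base
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("log_tpm", class(out))
  out
}
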