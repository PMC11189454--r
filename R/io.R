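# Canonical dialect: TSV, UTF-8, header row mandatory, first column the
# gene/ROI identifier. Count matrices additionally support MatrixMarket
# (matrix.mtx + rows.txt + cols.txt).

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

tsv_to_matrix <- function(path) {
  df <- read_tsv_strict(path)
  ids <- as.character(df[[1L]])
  check_unique(ids, paste0("row identifier in ", basename(path)))
  m <- as.matrix(df[-1L])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

matrix_to_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x ROI count matrix
#'
#' @param path TSV file (gene rows, ROI columns, header row, first column the
#'   gene symbol), or for `format = "mtx"` the MatrixMarket file, with row and
#'   column name files alongside.
#' @param format `"tsv"` or `"mtx"`.
#' @param rows,cols for MTX input, paths of the newline-separated gene and ROI
#'   name files; default `<path-dir>/rows.txt` and `cols.txt`.
#' @return A validated [count_matrix()]; file ordering preserved.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              rows = NULL, cols = NULL) {
  format <- match.arg(format)
  if (format == "tsv") return(count_matrix(tsv_to_matrix(path)))
  if (!file.exists(path)) abort_validation("file not found: ", path)
  if (is.null(rows)) rows <- file.path(dirname(path), "rows.txt")
  if (is.null(cols)) cols <- file.path(dirname(path), "cols.txt")
  m <- as.matrix(Matrix::readMM(path))
  rn <- readLines(rows); cn <- readLines(cols)
  if (length(rn) != nrow(m) || length(cn) != ncol(m))
    abort_validation("MTX dimensions (", nrow(m), " x ", ncol(m),
                     ") do not match name files (", length(rn), ", ", length(cn), ")")
  dimnames(m) <- list(rn, cn)
  count_matrix(m)
}

#' Write a count matrix
#'
#' @param x a [count_matrix()].
#' @param path output path (TSV) or MTX file for `format = "mtx"`.
#' @param format `"tsv"` or `"mtx"` (writes `rows.txt`/`cols.txt` alongside).
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") return(matrix_to_tsv(x, path))
  Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
  writeLines(rownames(x), file.path(dirname(path), "rows.txt"))
  writeLines(colnames(x), file.path(dirname(path), "cols.txt"))
  invisible(path)
}

#' Read / write an expression matrix
#'
#' TSV of the same layout as a count matrix; the scale is supplied by the
#' caller on read and is not stored in the file.
#'
#' @param path TSV path.
#' @param scale `"normalized"` or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("normalized", "log2")) {
  expression_matrix(tsv_to_matrix(path), match.arg(scale))
}

#' @rdname read_expression_matrix
#' @param x an `expression_matrix`.
#' @export
write_expression_matrix <- function(x, path) matrix_to_tsv(x, path)

#' Read a per-ROI annotation table
#' @param path TSV with the columns documented in [roi_annotation()].
#' @return A validated `roi_annotation`.
#' @export
read_annotation <- function(path) roi_annotation(read_tsv_strict(path))

#' @rdname read_annotation
#' @param x a `roi_annotation`.
#' @export
write_annotation <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-target prior table
#' @param path TSV with columns `ligand`, `target`, `weight`.
#' @return A validated `ligand_target_prior`.
#' @export
read_prior <- function(path) ligand_target_prior(read_tsv_strict(path))

#' @rdname read_prior
#' @param x a `ligand_target_prior`.
#' @export
write_prior <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a layered signalling network edge list
#' @param path TSV with columns `source`, `target`, `weight`, `layer`.
#' @return A validated `signalling_network`.
#' @export
read_network <- function(path) signalling_network(read_tsv_strict(path))

#' @rdname read_network
#' @param x a `signalling_network`.
#' @export
write_network <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-profile signature matrix
#' @param path TSV, gene rows x cell-type columns.
#' @return A validated `cell_profile_matrix`.
#' @export
read_profiles <- function(path) cell_profile_matrix(tsv_to_matrix(path))

#' @rdname read_profiles
#' @param x a `cell_profile_matrix`.
#' @export
write_profiles <- function(x, path) matrix_to_tsv(x, path)

#' Read a subtype centroid matrix
#' @param path TSV, gene rows x subtype columns.
#' @return A validated `centroid_matrix`.
#' @export
read_centroids <- function(path) centroid_matrix(tsv_to_matrix(path))

#' @rdname read_centroids
#' @param x a `centroid_matrix`.
#' @export
write_centroids <- function(x, path) matrix_to_tsv(x, path)
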