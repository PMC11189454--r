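COMPARTMENTS <- c("tumour", "stroma", "immune")
NETWORK_LAYERS <- c("ligand_receptor", "signalling", "gene_regulatory")

abort_validation <- function(...) {
  stop(structure(class = c("roicrosstalk_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0L)
    abort_validation("duplicate ", what, ": ", paste(d, collapse = ", "))
  invisible(x)
}

#' Construct a validated gene x ROI count matrix
#'
#' Counts are the raw input of the pipeline: one row per gene symbol, one
#' column per region of interest (ROI), non-negative integers. Gene and ROI
#' identifiers must be unique; matching against other tables is by exact
#' string.
#'
#' @param counts numeric matrix with rownames (genes) and colnames (ROIs).
#' @return A `count_matrix` (an integer-valued matrix with class attribute).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_validation("count matrix requires gene rownames and ROI colnames")
  check_unique(rownames(counts), "gene identifier")
  check_unique(colnames(counts), "ROI identifier")
  if (!is.numeric(counts))
    abort_validation("count matrix must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort_validation("negative or non-integer count at gene '",
                     rownames(counts)[bad[1L, 1L]], "', ROI '",
                     colnames(counts)[bad[1L, 2L]], "'")
  storage.mode(counts) <- "double"
  structure(counts, class = c("count_matrix", "matrix", "array"))
}

#' Construct a validated expression matrix
#'
#' Same shape as a count matrix but real-valued, tagged with the scale it
#' lives on: `"normalized"` (linear, non-negative, post-Q3) or `"log2"`.
#'
#' @param values numeric matrix with gene rownames and ROI colnames.
#' @param scale one of `"normalized"`, `"log2"`.
#' @return An `expression_matrix` with a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("normalized", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_validation("expression matrix requires gene rownames and ROI colnames")
  check_unique(rownames(values), "gene identifier")
  check_unique(colnames(values), "ROI identifier")
  if (any(!is.finite(values)))
    abort_validation("expression matrix contains non-finite values")
  if (scale == "normalized" && any(values < 0))
    abort_validation("normalized expression must be non-negative")
  structure(values, scale = scale,
            class = c("expression_matrix", "matrix", "array"))
}

#' Scale tag of an expression matrix
#' @param x an `expression_matrix`.
#' @return `"normalized"` or `"log2"`.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Construct a validated per-ROI annotation table
#'
#' One row per ROI with its tissue-microarray core, donor, compartment label
#' (tumour / stroma / immune) and the sequencing QC metrics used by
#' [filter_rois()].
#'
#' @param df data.frame with columns `roi_id`, `core_id`, `donor_id`,
#'   `compartment`, `raw_reads`, `saturation`, `pct_aligned`, `pct_trimmed`,
#'   `pct_stitched`.
#' @return A validated `roi_annotation` data.frame.
#' @export
roi_annotation <- function(df) {
  req <- c("roi_id", "core_id", "donor_id", "compartment", "raw_reads",
           "saturation", "pct_aligned", "pct_trimmed", "pct_stitched")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    abort_validation("annotation missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$roi_id <- as.character(df$roi_id)
  df$core_id <- as.character(df$core_id)
  df$donor_id <- as.character(df$donor_id)
  df$compartment <- as.character(df$compartment)
  check_unique(df$roi_id, "ROI identifier")
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad) > 0L)
    abort_validation("compartment value(s) outside {",
                     paste(COMPARTMENTS, collapse = ", "), "}: ",
                     paste(bad, collapse = ", "))
  for (col in c("saturation", "pct_aligned", "pct_trimmed", "pct_stitched")) {
    v <- df[[col]]
    if (any(!is.finite(v) | v < 0 | v > 100))
      abort_validation(col, " must lie in [0, 100]")
  }
  if (any(!is.finite(df$raw_reads) | df$raw_reads < 0))
    abort_validation("raw_reads must be a non-negative count")
  structure(df, class = c("roi_annotation", "data.frame"))
}

#' Construct a validated ligand-target prior
#'
#' Each row scores how strongly `ligand` is expected to regulate `target`
#' (regulatory potential, weight >= 0), in the shape of a NicheNet-style
#' ligand-target matrix melted to long form.
#'
#' @param df data.frame with columns `ligand`, `target`, `weight`.
#' @return A validated `ligand_target_prior` data.frame.
#' @export
ligand_target_prior <- function(df) {
  req <- c("ligand", "target", "weight")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    abort_validation("prior missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$ligand <- as.character(df$ligand)
  df$target <- as.character(df$target)
  check_unique(paste(df$ligand, df$target, sep = "\r"), "(ligand, target) pair")
  if (any(!is.finite(df$weight) | df$weight < 0))
    abort_validation("prior weights must be non-negative")
  structure(df, class = c("ligand_target_prior", "data.frame"))
}

#' Construct a validated layered signalling network
#'
#' Directed weighted edges in three layers: `ligand_receptor` (a ligand's
#' first hop), `signalling` (receptor/kinase cascades) and `gene_regulatory`
#' (transcription-factor to target). Weights are interaction potentials in
#' (0, 1]; self-loops are rejected.
#'
#' @param df data.frame with columns `source`, `target`, `weight`, `layer`.
#' @return A validated `signalling_network` data.frame.
#' @export
signalling_network <- function(df) {
  req <- c("source", "target", "weight", "layer")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    abort_validation("network missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  df$layer <- as.character(df$layer)
  if (any(!is.finite(df$weight) | df$weight <= 0 | df$weight > 1))
    abort_validation("network weights must lie in (0, 1]")
  bad <- setdiff(unique(df$layer), NETWORK_LAYERS)
  if (length(bad) > 0L)
    abort_validation("network layer(s) outside {",
                     paste(NETWORK_LAYERS, collapse = ", "), "}: ",
                     paste(bad, collapse = ", "))
  if (any(df$source == df$target))
    abort_validation("network contains self-loop(s)")
  structure(df, class = c("signalling_network", "data.frame"))
}

#' Construct a validated cell-profile signature matrix
#'
#' Mean linear-scale expression of each gene in each cell type, derived from
#' a single-cell reference; the design matrix of the deconvolution.
#'
#' @param mat numeric matrix, genes x cell types, non-negative.
#' @return A `cell_profile_matrix`.
#' @export
cell_profile_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    abort_validation("profile matrix requires gene rownames and cell-type colnames")
  check_unique(rownames(mat), "gene identifier")
  check_unique(colnames(mat), "cell type")
  if (ncol(mat) < 2L)
    abort_validation("profile matrix needs at least 2 cell types")
  if (any(!is.finite(mat) | mat < 0))
    abort_validation("profile matrix must be non-negative and finite")
  structure(mat, class = c("cell_profile_matrix", "matrix", "array"))
}

#' Construct a validated subtype centroid matrix
#'
#' Per-subtype centroid expression over a gene panel, e.g. the six consensus
#' muscle-invasive bladder cancer classes (LumP, LumNS, LumU, Basal,
#' Stroma-rich, NE-like). Centroids are pluggable: any >= 2 labelled columns.
#'
#' @param mat numeric matrix, genes x subtypes.
#' @return A `centroid_matrix`.
#' @export
centroid_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    abort_validation("centroid matrix requires gene rownames and subtype colnames")
  check_unique(rownames(mat), "gene identifier")
  check_unique(colnames(mat), "subtype label")
  if (ncol(mat) < 2L)
    abort_validation("centroid matrix needs at least 2 subtypes")
  if (any(!is.finite(mat)))
    abort_validation("centroid matrix must be finite")
  structure(mat, class = c("centroid_matrix", "matrix", "array"))
}

#' Check that a count/expression matrix and an annotation cover the same ROIs
#'
#' Consumers joining a matrix with its annotation must see identical ROI sets;
#' on mismatch the symmetric difference is reported.
#'
#' @param mat matrix with ROI colnames.
#' @param annot a `roi_annotation`.
#' @return invisibly, the shared ROI ids (in matrix column order).
#' @export
check_roi_match <- function(mat, annot) {
  a <- colnames(mat); b <- annot$roi_id
  only_mat <- setdiff(a, b); only_ann <- setdiff(b, a)
  if (length(only_mat) > 0L || length(only_ann) > 0L)
    abort_validation(
      "ROI sets differ between matrix and annotation; only in matrix: {",
      paste(only_mat, collapse = ", "), "}; only in annotation: {",
      paste(only_ann, collapse = ", "), "}")
  invisible(a)
}
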