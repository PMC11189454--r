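# Nearest-centroid molecular subtyping with an "undefined" class.

#' Classify ROIs against subtype centroids
#'
#' Each ROI's log2 expression over the genes shared with the centroid panel
#' is Pearson-correlated with every subtype centroid. The call is the argmax
#' subtype when the best correlation reaches `min_corr`, otherwise
#' `"undefined"` — ROIs not enriched for any subtype signature stay
#' unassigned. Ties are broken by lexicographic subtype label and flagged.
#' Pearson invariance makes the call unaffected by per-ROI affine transforms
#' of expression.
#'
#' @param expr an [expression_matrix()] on the `"log2"` scale.
#' @param centroids a [centroid_matrix()] sharing >= 20 genes with `expr`.
#' @param min_corr minimum best correlation for a defined call (default 0.2).
#' @return data.frame: `roi_id`, one correlation column per subtype
#'   (`r_<label>`), `label`, `best_r`, `separation` (best minus second-best
#'   correlation), `tied`.
#' @export
classify_subtypes <- function(expr, centroids, min_corr = 0.2) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(centroids, "centroid_matrix"))
  if (expr_scale(expr) != "log2")
    abort_validation("classify_subtypes expects log2-scale expression")
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < 20L)
    abort_validation("only ", length(shared),
                     " genes shared with centroids; need >= 20")
  E <- unclass(expr)[shared, , drop = FALSE]
  C <- unclass(centroids)[shared, , drop = FALSE]
  R <- stats::cor(E, C)  # ROI x subtype
  labels <- colnames(C)[order(colnames(C))]
  R <- R[, labels, drop = FALSE]  # lexicographic order => which.max tie-break

  best_i <- apply(R, 1L, which.max)
  best_r <- R[cbind(seq_len(nrow(R)), best_i)]
  second <- apply(R, 1L, function(r) sort(r, decreasing = TRUE)[2L])
  tied <- apply(R, 1L, function(r) sum(r == max(r)) > 1L)
  label <- ifelse(best_r >= min_corr, labels[best_i], "undefined")

  out <- data.frame(roi_id = rownames(R), stringsAsFactors = FALSE)
  for (s in labels) out[[paste0("r_", s)]] <- R[, s]
  out$label <- label
  out$best_r <- best_r
  out$separation <- best_r - second
  out$tied <- tied
  rownames(out) <- NULL
  out
}
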