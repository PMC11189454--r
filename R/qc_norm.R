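# ROI/gene QC and Q3 normalisation.
#
# Inequality conventions follow the source pipeline's printed thresholds:
# "minimum raw reads (1000)" is >= 1000; saturation and the percent
# aligned/trimmed/stitched rules are strict (> 50, > 80); "ROIs with less
# than 10% of genes expressed were removed" keeps an ROI at >= 10%; genes are
# kept when detected in strictly more than the detection fraction of ROIs.

#' QC thresholds for ROI and gene filtering
#'
#' @param min_raw_reads ROI kept if raw reads >= this (default 1000).
#' @param min_saturation ROI kept if sequencing saturation strictly exceeds
#'   this percentage (default 50).
#' @param min_pct ROI kept if each of percent aligned / trimmed / stitched
#'   strictly exceeds this percentage (default 80).
#' @param min_genes_detected_frac ROI kept if the fraction of genes with
#'   count > `detect_min_count` is >= this (default 0.10).
#' @param gene_detection_frac gene kept if detected in strictly more than
#'   this fraction of kept ROIs (default 0.10).
#' @param detect_min_count a gene counts as detected in an ROI when its raw
#'   count is >= this (default 1, i.e. count > 0).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_raw_reads = 1000, min_saturation = 50,
                          min_pct = 80, min_genes_detected_frac = 0.10,
                          gene_detection_frac = 0.10, detect_min_count = 1) {
  stopifnot(min_raw_reads >= 0,
            min_saturation >= 0, min_saturation <= 100,
            min_pct >= 0, min_pct <= 100,
            min_genes_detected_frac >= 0, min_genes_detected_frac <= 1,
            gene_detection_frac >= 0, gene_detection_frac <= 1,
            detect_min_count > 0)
  structure(list(min_raw_reads = min_raw_reads,
                 min_saturation = min_saturation,
                 min_pct = min_pct,
                 min_genes_detected_frac = min_genes_detected_frac,
                 gene_detection_frac = gene_detection_frac,
                 detect_min_count = detect_min_count),
            class = "qc_thresholds")
}

#' Filter ROIs on sequencing QC and gene-detection rate
#'
#' An ROI is kept iff it passes every rule: `raw_reads >= min_raw_reads`,
#' `saturation > min_saturation`, each of `pct_aligned`, `pct_trimmed`,
#' `pct_stitched` `> min_pct`, and the fraction of panel genes detected
#' (count >= `detect_min_count`) is `>= min_genes_detected_frac`. The report
#' names every rule each excluded ROI failed.
#'
#' @param counts a [count_matrix()].
#' @param annot a [roi_annotation()] covering exactly the matrix's ROIs.
#' @param th a [qc_thresholds()].
#' @return list with `counts` (kept-ROI subset), `annot` (matching subset) and
#'   `report` (a `qc_report`: per-ROI `pass` flag and `failed_rules`).
#' @export
filter_rois <- function(counts, annot, th = qc_thresholds()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(annot, "roi_annotation"))
  check_roi_match(counts, annot)
  annot <- annot[match(colnames(counts), annot$roi_id), , drop = FALSE]

  detect_frac <- colMeans(unclass(counts) >= th$detect_min_count)
  rules <- list(
    min_raw_reads   = annot$raw_reads >= th$min_raw_reads,
    min_saturation  = annot$saturation > th$min_saturation,
    min_pct_aligned = annot$pct_aligned > th$min_pct,
    min_pct_trimmed = annot$pct_trimmed > th$min_pct,
    min_pct_stitched = annot$pct_stitched > th$min_pct,
    min_genes_detected_frac = detect_frac >= th$min_genes_detected_frac)
  pass_mat <- do.call(cbind, rules)
  keep <- rowSums(!pass_mat) == 0L
  failed <- apply(pass_mat, 1L, function(p) names(rules)[!p], simplify = FALSE)
  names(failed) <- annot$roi_id

  if (!any(keep))
    abort_validation("all ", length(keep), " ROIs fail QC; nothing to analyse")

  report <- structure(list(
    roi = data.frame(roi_id = annot$roi_id, pass = keep,
                     failed_rules = vapply(failed, paste, "", collapse = ";"),
                     stringsAsFactors = FALSE),
    failed_rules = failed[!keep],
    kept_roi_ids = annot$roi_id[keep],
    removed_roi_ids = annot$roi_id[!keep],
    n_removed_rois = sum(!keep)), class = "qc_report")

  list(counts = count_matrix(unclass(counts)[, keep, drop = FALSE]),
       annot = roi_annotation(annot[keep, , drop = FALSE]),
       report = report)
}

#' Filter genes on detection fraction across kept ROIs
#'
#' A gene is kept iff it is detected (count >= `detect_min_count`) in strictly
#' more than `frac` of the ROIs. Run after [filter_rois()].
#'
#' @param counts a ROI-filtered [count_matrix()].
#' @param frac detection fraction in \[0, 1\] (default 0.10).
#' @param detect_min_count detection limit (default 1).
#' @return list with `counts` (kept-gene subset) and `report` (kept/removed
#'   gene ids and counts).
#' @export
filter_genes <- function(counts, frac = 0.10, detect_min_count = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.finite(frac) || frac < 0 || frac > 1)
    abort_validation("gene detection fraction must lie in [0, 1], got ", frac)
  detect_frac <- rowMeans(unclass(counts) >= detect_min_count)
  keep <- detect_frac > frac
  if (!any(keep))
    abort_validation("all genes fail the detection filter")
  report <- structure(list(
    gene = data.frame(gene_id = rownames(counts), detect_frac = detect_frac,
                      pass = keep, stringsAsFactors = FALSE),
    kept_gene_ids = rownames(counts)[keep],
    removed_gene_ids = rownames(counts)[!keep],
    n_removed_genes = sum(!keep)), class = "qc_report")
  list(counts = count_matrix(unclass(counts)[keep, , drop = FALSE]),
       report = report)
}

#' Q3 (third-quartile) normalisation
#'
#' Each ROI is scaled by its 75th percentile of counts over the retained
#' genes (linear-interpolation percentile, `quantile type = 7`), anchored so
#' that every ROI's post-normalisation Q3 equals the geometric mean of the
#' per-ROI Q3s: `normalized = count * gm(q3) / q3_roi`.
#'
#' @param counts a QC-filtered [count_matrix()].
#' @return An [expression_matrix()] on the `"normalized"` scale.
#' @export
q3_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- unclass(counts)
  q3 <- apply(m, 2L, stats::quantile, probs = 0.75, names = FALSE, type = 7)
  zero <- q3 <= 0
  if (any(zero))
    abort_validation("ROI(s) with zero third quartile (should have failed QC): ",
                     paste(colnames(m)[zero], collapse = ", "))
  gm <- exp(mean(log(q3)))
  expression_matrix(sweep(m, 2L, gm / q3, `*`), "normalized")
}

#' Log2 transform of normalized expression
#'
#' @param expr an [expression_matrix()] on the `"normalized"` scale.
#' @param offset positive pseudo-count added before taking log2 (default 1).
#' @return An [expression_matrix()] on the `"log2"` scale.
#' @export
log2_transform <- function(expr, offset = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr_scale(expr) != "normalized")
    abort_validation("log2_transform expects a 'normalized' matrix, got '",
                     expr_scale(expr), "'")
  if (!is.finite(offset) || offset <= 0)
    abort_validation("offset must be positive")
  if (any(expr < 0)) abort_validation("negative input to log2 transform")
  expression_matrix(log2(unclass(expr) + offset), "log2")
}
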