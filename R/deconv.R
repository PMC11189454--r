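# Signature-matrix cell-type deconvolution: per-ROI non-negative least
# squares of linear-scale expression on the cell-profile matrix, proportions
# taken as the normalised coefficients.

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b||_2 subject to x >= 0. Self-contained so the
#' deconvolution has no solver dependency; problems here are small (tens of
#' columns).
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol tolerance on the dual feasibility test.
#' @return list with `x` (coefficients) and `resid_norm`.
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L; max_iter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  list(x = as.numeric(x), resid_norm = sqrt(sum((b - A %*% x)^2)))
}

select_signature_genes <- function(profiles, top_n = 50L) {
  # top_n genes per cell type by fold difference over the mean of the others
  m <- unclass(profiles)
  k <- ncol(m)
  eps <- 1e-9
  picks <- lapply(seq_len(k), function(j) {
    other <- rowMeans(m[, -j, drop = FALSE])
    fold <- (m[, j] + eps) / (other + eps)
    rownames(m)[order(-fold, rownames(m))][seq_len(min(top_n, nrow(m)))]
  })
  unique(unlist(picks))
}

#' Estimate per-ROI cell-type proportions
#'
#' For every ROI, solves non-negative least squares `y ~ P beta` over the
#' genes shared between the expression matrix and the profile matrix
#' (optionally restricted to a signature gene set), and reports
#' `beta / sum(beta)` plus the residual norm. Proportions are scale
#' invariant: multiplying an ROI by a constant leaves them unchanged.
#'
#' @param expr an [expression_matrix()] on the `"normalized"` (linear) scale.
#' @param profiles a [cell_profile_matrix()].
#' @param signature_genes optional character vector restricting the fit;
#'   `NULL` (default) selects the top `signature_top_n` genes per cell type
#'   by fold difference over the mean of the other types; `NA` uses all
#'   shared genes.
#' @param signature_top_n genes per cell type for the default selection.
#' @return list with `proportions` (ROI x cell-type matrix, rows summing
#'   to 1), `resid_norm` (per ROI) and `genes_used`.
#' @export
estimate_proportions <- function(expr, profiles, signature_genes = NULL,
                                 signature_top_n = 50L) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(profiles, "cell_profile_matrix"))
  if (expr_scale(expr) != "normalized")
    abort_validation("deconvolution expects linear 'normalized' expression")
  if (is.null(signature_genes)) {
    signature_genes <- select_signature_genes(profiles, signature_top_n)
  } else if (length(signature_genes) == 1L && is.na(signature_genes)) {
    signature_genes <- rownames(profiles)
  }
  shared <- intersect(intersect(rownames(expr), rownames(profiles)),
                      signature_genes)
  k <- ncol(profiles)
  if (length(shared) < k)
    abort_validation("only ", length(shared), " shared genes for ", k,
                     " cell types; need at least as many genes as types")
  P <- unclass(profiles)[shared, , drop = FALSE]
  Y <- unclass(expr)[shared, , drop = FALSE]
  props <- matrix(NA_real_, ncol(Y), k,
                  dimnames = list(colnames(Y), colnames(profiles)))
  resid <- numeric(ncol(Y)); names(resid) <- colnames(Y)
  for (j in seq_len(ncol(Y))) {
    fit <- nnls_fit(P, Y[, j])
    s <- sum(fit$x)
    if (s <= 0)
      abort_validation("ROI '", colnames(Y)[j],
                       "' is non-decomposable (all-zero NNLS solution)")
    props[j, ] <- fit$x / s
    resid[j] <- fit$resid_norm
  }
  list(proportions = props, resid_norm = resid, genes_used = shared)
}
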