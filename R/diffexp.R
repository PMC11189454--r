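# Two-group differential expression with empirical-Bayes variance moderation.
#
# Model: per-gene pooled residual variance s^2 with d = n_a + n_b - 2 df is
# assumed s^2 | sigma^2 ~ sigma^2 chi^2_d / d with a scaled inverse-chi^2
# prior (d0, s0^2) on sigma^2, so marginally s^2 ~ s0^2 F(d, d0). The
# hyperparameters are fitted by method of moments on log s^2: with
# z = log s^2, E[z] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2)
# + log(d0/2) and Var[z] = trigamma(d/2) + trigamma(d0/2). Posterior
# variance s~^2 = (d0 s0^2 + d s^2)/(d0 + d); the moderated t uses d0 + d df.

trigamma_inverse <- function(x) {
  # solve trigamma(y) = x by the standard Newton iteration on 1/trigamma
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

fit_fdist_moments <- function(s2, df) {
  x <- pmax(s2[is.finite(s2)], 0)
  med <- stats::median(x)
  if (med == 0) med <- 1
  x <- pmax(x, 1e-5 * med)  # guard against exact zeros
  e <- log(x) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- mean(x)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-test (empirical-Bayes variance shrinkage)
#'
#' For each gene, computes the difference of group means on the log2 scale,
#' the pooled residual variance, and a moderated t statistic in which the
#' per-gene variance is shrunk towards a prior value fitted across genes by
#' moment matching of `log(s^2)` to a scaled-F model. With `d0 = 0` the
#' statistic reduces exactly to the ordinary pooled two-sample t.
#'
#' @param expr an [expression_matrix()] on the `"log2"` scale.
#' @param group_a,group_b disjoint character vectors of ROI ids, each of
#'   size >= 2. The log2 fold change is mean(A) - mean(B).
#' @param d0,s02 optional hyperparameter overrides; both must be given
#'   together. `d0 = 0` gives the unmoderated pooled t; `d0 = Inf` fixes the
#'   variance at `s02` for every gene.
#' @return A data.frame (one row per gene): `gene_id`, `log2fc`, `s2`, `t`,
#'   `p_value`, `adj_p_value`, `var_floored` (zero-variance genes floored to
#'   the smallest positive `s2`), plus attributes `d0`, `s02`, `n_a`, `n_b`.
#' @export
moderated_t <- function(expr, group_a, group_b, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr_scale(expr) != "log2")
    abort_validation("moderated_t expects log2-scale expression")
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)) > 0L)
    abort_validation("groups must be disjoint")
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss) > 0L)
    abort_validation("ROIs not in matrix: ", paste(miss, collapse = ", "))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    abort_validation("each group needs >= 2 ROIs (got ", na, " and ", nb, ")")

  A <- unclass(expr)[, group_a, drop = FALSE]
  B <- unclass(expr)[, group_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  d <- na + nb - 2
  s2 <- (ssa + ssb) / d
  if (all(s2 == 0)) abort_validation("all genes have zero residual variance")

  floored <- s2 == 0
  s2[floored] <- min(s2[!floored])

  if (is.null(d0) != is.null(s02))
    abort_validation("d0 and s02 must be supplied together")
  if (is.null(d0)) {
    fit <- fit_fdist_moments(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  tt <- (ma - mb) / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- d0 + d
  p <- 2 * stats::pt(abs(tt), df = df_total, lower.tail = FALSE)

  out <- data.frame(gene_id = rownames(expr), log2fc = ma - mb, s2 = s2,
                    t = tt, p_value = p, adj_p_value = bh_adjust(p),
                    var_floored = floored, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0; attr(out, "s02") <- s02
  attr(out, "n_a") <- na; attr(out, "n_b") <- nb
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    abort_validation("p-values must be finite and in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
}

#' Gene-set over-representation (one-sided hypergeometric)
#'
#' For each named gene set, the probability of observing at least the seen
#' overlap between `gene_list` and the set, drawing `length(gene_list)` genes
#' without replacement from `universe`. Sets are intersected with the
#' universe first; BH adjustment is applied across sets.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all testable genes.
#' @return data.frame: `set`, `set_size` (in-universe), `overlap`, `p_value`,
#'   `adj_p_value`.
#' @export
enrich <- function(gene_list, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort_validation("empty universe")
  gene_list <- unique(as.character(gene_list))
  out <- setdiff(gene_list, universe)
  if (length(out) > 0L)
    abort_validation("gene_list not contained in universe: ",
                     paste(utils::head(out, 5L), collapse = ", "))
  n_draw <- length(gene_list)
  N <- length(universe)
  res <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(as.character(gene_sets[[nm]])), universe)
    k <- length(intersect(gene_list, gs))
    p <- stats::phyper(k - 1L, length(gs), N - length(gs), n_draw,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adj_p_value <- bh_adjust(res$p_value)
  res
}
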