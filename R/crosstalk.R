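# Paired sender -> receiver ligand-activity scoring.
#
# Tissue-microarray cores are the adjacency unit: the sender-compartment and
# receiver-compartment ROIs of one core are physically adjacent, so a ligand
# expressed in the sender side of a core should, if actively signalling,
# covary across cores with its prior target genes on the receiver side.
# Activity of a ligand = mean Pearson correlation, across cores, between the
# ligand's sender-profile expression and each retained target's
# receiver-profile expression; mean r >= 0.2 calls the ligand active.

#' Configuration of the ligand-activity computation
#'
#' @param activity_threshold mean per-target Pearson r at or above which a
#'   ligand is called active (default 0.2).
#' @param top_k_targets_per_ligand per ligand, keep at most this many prior
#'   targets, highest regulatory potential first (default 200; `Inf` keeps
#'   every in-dataset pair).
#' @param min_targets_present drop ligands with fewer surviving targets
#'   (default 5).
#' @param min_pairs minimum number of core pairs for any correlation
#'   (default 3).
#' @return A `crosstalk_config` list.
#' @export
crosstalk_config <- function(activity_threshold = 0.2,
                             top_k_targets_per_ligand = 200,
                             min_targets_present = 5L, min_pairs = 3L) {
  stopifnot(activity_threshold > -1, activity_threshold < 1,
            min_targets_present >= 2L,
            top_k_targets_per_ligand >= min_targets_present,
            min_pairs >= 3L)
  structure(list(activity_threshold = activity_threshold,
                 top_k_targets_per_ligand = top_k_targets_per_ligand,
                 min_targets_present = as.integer(min_targets_present),
                 min_pairs = as.integer(min_pairs)),
            class = "crosstalk_config")
}

#' Build within-core sender/receiver profile pairs
#'
#' For every core holding at least one ROI of the sender compartment and at
#' least one of the receiver compartment, emits one pair: the per-gene
#' arithmetic mean over the core's sender-compartment ROIs, and likewise for
#' the receiver compartment. Cores lacking either compartment are skipped and
#' listed. Sender may equal receiver (within-compartment signalling), in
#' which case the two profiles coincide.
#'
#' @param annot a [roi_annotation()].
#' @param expr an [expression_matrix()] on the `"log2"` scale, QC-filtered.
#' @param sender,receiver compartments from `{tumour, stroma, immune}`.
#' @param min_pairs error if fewer pairs result (default 3).
#' @return A `roi_pairing`: list with `core_ids`, `sender_profiles` and
#'   `receiver_profiles` (gene x core matrices), `sender`, `receiver`,
#'   `skipped_cores`.
#' @export
build_pairs <- function(annot, expr, sender, receiver, min_pairs = 3L) {
  stopifnot(inherits(annot, "roi_annotation"),
            inherits(expr, "expression_matrix"))
  if (expr_scale(expr) != "log2")
    abort_validation("build_pairs expects log2-scale expression")
  if (!sender %in% COMPARTMENTS || !receiver %in% COMPARTMENTS)
    abort_validation("sender/receiver must be one of ",
                     paste(COMPARTMENTS, collapse = ", "))
  check_roi_match(expr, annot)
  annot <- annot[match(colnames(expr), annot$roi_id), , drop = FALSE]

  cores <- unique(annot$core_id)
  profile_for <- function(core, comp) {
    ids <- annot$roi_id[annot$core_id == core & annot$compartment == comp]
    if (length(ids) == 0L) return(NULL)
    rowMeans(unclass(expr)[, ids, drop = FALSE])
  }
  s_list <- lapply(cores, profile_for, comp = sender)
  r_list <- lapply(cores, profile_for, comp = receiver)
  ok <- !vapply(s_list, is.null, TRUE) & !vapply(r_list, is.null, TRUE)
  if (sum(ok) < min_pairs)
    abort_validation("only ", sum(ok), " ", sender, "->", receiver,
                     " core pairs; need at least ", min_pairs)
  sp <- do.call(cbind, s_list[ok]); colnames(sp) <- cores[ok]
  rp <- do.call(cbind, r_list[ok]); colnames(rp) <- cores[ok]
  structure(list(
    core_ids = cores[ok],
    sender_profiles = sp,
    receiver_profiles = rp,
    sender = sender, receiver = receiver,
    skipped_cores = cores[!ok]), class = "roi_pairing")
}

#' Restrict a ligand-target prior to the measured gene universe
#'
#' Keeps pairs whose ligand and target are both present; per ligand retains
#' the `top_k_targets_per_ligand` highest-weight pairs (ties broken by
#' lexicographic target symbol) and drops ligands left with fewer than
#' `min_targets_present` targets.
#'
#' @param prior a [ligand_target_prior()].
#' @param genes_present character vector of measured gene symbols.
#' @param cfg a [crosstalk_config()].
#' @return A restricted `ligand_target_prior`.
#' @export
restrict_prior <- function(prior, genes_present, cfg = crosstalk_config()) {
  stopifnot(inherits(prior, "ligand_target_prior"))
  keep <- prior$ligand %in% genes_present & prior$target %in% genes_present
  df <- as.data.frame(prior)[keep, , drop = FALSE]
  if (nrow(df) > 0L) {
    df <- df[order(df$ligand, -df$weight, df$target), , drop = FALSE]
    df <- do.call(rbind, lapply(split(df, df$ligand), function(g) {
      g <- utils::head(g, cfg$top_k_targets_per_ligand)
      if (nrow(g) < cfg$min_targets_present) NULL else g
    }))
  }
  if (is.null(df) || nrow(df) == 0L)
    abort_validation("prior restriction left no usable ligand")
  rownames(df) <- NULL
  ligand_target_prior(df)
}

#' Ligand-activity scores across paired sender/receiver profiles
#'
#' For each ligand in the (restricted) prior: let `x` be the ligand's
#' expression across the pairs' sender profiles and, for each retained target
#' `t`, `y_t` its expression across the same pairs' receiver profiles.
#' Activity is the arithmetic mean of `cor(x, y_t)` over targets; a ligand is
#' active when activity >= `cfg$activity_threshold`. Targets with zero
#' variance are skipped and counted; ligands whose sender expression is
#' constant are returned flagged `evaluable = FALSE` rather than dropped.
#'
#' @param pairs a [build_pairs()] result.
#' @param prior a [restrict_prior()]-processed prior.
#' @param cfg a [crosstalk_config()].
#' @return list with `activity` (data.frame: `ligand`, `sender`, `receiver`,
#'   `activity`, `n_targets_used`, `n_targets_skipped`, `n_pairs`, `active`,
#'   `evaluable`) and `target_r` (data.frame of per-target correlations:
#'   `ligand`, `target`, `r`).
#' @export
ligand_activity <- function(pairs, prior, cfg = crosstalk_config()) {
  stopifnot(inherits(pairs, "roi_pairing"),
            inherits(prior, "ligand_target_prior"))
  n_pairs <- length(pairs$core_ids)
  if (n_pairs < cfg$min_pairs)
    abort_validation(n_pairs, " pairs < min_pairs = ", cfg$min_pairs)
  S <- pairs$sender_profiles; R <- pairs$receiver_profiles
  ligands <- intersect(unique(prior$ligand), rownames(S))

  act_rows <- vector("list", length(ligands))
  tr_rows <- vector("list", length(ligands))
  for (i in seq_along(ligands)) {
    lig <- ligands[i]
    x <- S[lig, ]
    targets <- prior$target[prior$ligand == lig]
    targets <- targets[targets %in% rownames(R)]
    if (stats::sd(x) == 0) {
      act_rows[[i]] <- data.frame(
        ligand = lig, sender = pairs$sender, receiver = pairs$receiver,
        activity = NA_real_, n_targets_used = 0L,
        n_targets_skipped = length(targets), n_pairs = n_pairs,
        active = FALSE, evaluable = FALSE, stringsAsFactors = FALSE)
      next
    }
    Y <- R[targets, , drop = FALSE]
    # zero-variance targets yield NA (sd-zero warning suppressed): handled
    # explicitly below as skipped targets
    r <- suppressWarnings(as.numeric(stats::cor(x, t(Y))))
    zero_var <- !is.finite(r)  # sd(y_t) == 0 gives NA
    r_ok <- r[!zero_var]
    used <- targets[!zero_var]
    activity <- if (length(r_ok) > 0L) mean(r_ok) else NA_real_
    act_rows[[i]] <- data.frame(
      ligand = lig, sender = pairs$sender, receiver = pairs$receiver,
      activity = activity, n_targets_used = length(r_ok),
      n_targets_skipped = sum(zero_var), n_pairs = n_pairs,
      active = is.finite(activity) && activity >= cfg$activity_threshold,
      evaluable = length(r_ok) > 0L, stringsAsFactors = FALSE)
    if (length(r_ok) > 0L)
      tr_rows[[i]] <- data.frame(ligand = lig, target = used, r = r_ok,
                                 stringsAsFactors = FALSE)
  }
  activity <- do.call(rbind, act_rows)
  rownames(activity) <- NULL
  target_r <- do.call(rbind, tr_rows)
  if (!is.null(target_r)) rownames(target_r) <- NULL
  list(activity = activity, target_r = target_r)
}

#' Permutation null for activity calibration
#'
#' Re-scores ligand activity after permuting the receiver profiles across
#' pairs, breaking the sender/receiver core coupling while preserving each
#' gene's marginal distribution. Used to calibrate the false-call rate of the
#' activity threshold; off the main path by default.
#'
#' @param pairs a [build_pairs()] result.
#' @param prior restricted prior.
#' @param cfg a [crosstalk_config()].
#' @param n_reps number of permutation replicates.
#' @param seed integer seed.
#' @return matrix of activities, ligands x replicates.
#' @export
activity_permutation_null <- function(pairs, prior, cfg = crosstalk_config(),
                                      n_reps = 200L, seed = 1L) {
  set.seed(seed)
  n <- length(pairs$core_ids)
  ligs <- NULL
  out <- matrix(NA_real_, 0, 0)
  for (b in seq_len(n_reps)) {
    perm <- sample.int(n)
    p2 <- pairs
    p2$receiver_profiles <- pairs$receiver_profiles[, perm, drop = FALSE]
    colnames(p2$receiver_profiles) <- colnames(pairs$receiver_profiles)
    res <- ligand_activity(p2, prior, cfg)$activity
    if (b == 1L) {
      ligs <- res$ligand
      out <- matrix(NA_real_, length(ligs), n_reps,
                    dimnames = list(ligs, NULL))
    }
    out[res$ligand, b] <- res$activity
  }
  out
}

#' Correlate ligand expression with deconvolved cell proportions
#'
#' Attributes the likely cellular origin of each ligand: Pearson correlation,
#' across shared ROIs, between the ligand's expression and each cell type's
#' deconvolved proportion. Edges with r strictly above the threshold are
#' returned.
#'
#' @param expr an [expression_matrix()] on the `"log2"` scale.
#' @param proportions ROI x cell-type matrix from [estimate_proportions()].
#' @param ligands character vector of ligand symbols to test.
#' @param r_threshold emit edges with r strictly greater (default 0.2).
#' @return list with `edges` (data.frame `cell_type`, `ligand`, `r`, filtered)
#'   and `all_r` (full matrix, ligands x cell types).
#' @export
correlate_ligands_with_cells <- function(expr, proportions, ligands,
                                         r_threshold = 0.2) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr_scale(expr) != "log2")
    abort_validation("correlate_ligands_with_cells expects log2 expression")
  shared <- intersect(colnames(expr), rownames(proportions))
  if (length(shared) < 3L)
    abort_validation("only ", length(shared),
                     " ROIs shared between expression and proportions; need >= 3")
  ligands <- intersect(ligands, rownames(expr))
  E <- t(unclass(expr)[ligands, shared, drop = FALSE])
  P <- proportions[shared, , drop = FALSE]
  all_r <- stats::cor(E, P)
  idx <- which(is.finite(all_r) & all_r > r_threshold, arr.ind = TRUE)
  edges <- data.frame(cell_type = colnames(all_r)[idx[, 2L]],
                      ligand = rownames(all_r)[idx[, 1L]],
                      r = all_r[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$r), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, all_r = all_r)
}
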