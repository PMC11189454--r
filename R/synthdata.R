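# Synthetic segmented-ROI dataset generator with full ground truth.
#
# World being emulated: a tissue-microarray cohort profiled as ~98 ROIs in
# three compartments (tumour / stroma / immune) paired within cores, with
# negative-binomial counts over log-normal library sizes, compartment-
# specific cell-type composition, planted ligand -> target couplings of a
# chosen population Pearson r, planted compartment DE markers, planted
# subtype signatures, and ROIs designed to fail exactly one named QC rule.
#
# Ligand coupling parameterisation: on the log2 scale a target's planted
# component is coupling * z + tau * eps with z the core-level sender latent
# and eps ~ N(0,1) per (core, target), tau = 1. The population correlation
# with the sender ligand (itself proportional to z) is then
# r = coupling / sqrt(coupling^2 + tau^2), so coupling = r / sqrt(1 - r^2)
# realises a requested population r exactly, before count noise.

#' Simulation configuration
#'
#' Defaults state the emulated cohort: 55 cores with compartment presence
#' probabilities 0.85 / 0.60 / 0.35 give ~98 expected ROIs in roughly the
#' 47 / 32 / 19 tumour / stroma / immune split; NB dispersion 0.2 and
#' log-normal library sizes (sdlog 0.35) are typical of targeted-panel
#' sequencing counts.
#'
#' @param n_cores number of tissue cores.
#' @param compartment_prob named presence probabilities for
#'   tumour / stroma / immune ROIs within a core.
#' @param n_genes total gene universe (partitioned internally into profile
#'   genes, ligands, target pools, subtype panel and DE markers).
#' @param n_cell_types number of cell types (max 8 named types).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param n_active_ligands,active_target_r,n_targets_per_active planted
#'   actively signalling ligands, their population Pearson r and target
#'   count; all planted sender -> receiver = `active_pair`.
#' @param active_pair length-2 character vector (sender, receiver).
#' @param n_null_ligands,n_targets_per_null null ligands (core-level
#'   variation but zero coupling).
#' @param n_de_genes_per_compartment,de_lfc planted compartment markers and
#'   their log2 fold change.
#' @param n_subtype_genes,subtype_r subtype signature panel size and the
#'   population correlation of planted subtype ROIs with their centroid.
#' @param qc_fail named integer counts of ROIs to corrupt, one rule each;
#'   names from `{min_raw_reads, min_saturation, min_pct_aligned,
#'   min_pct_trimmed, min_pct_stitched, min_genes_detected_frac}`.
#' @param seed mandatory integer seed; the generator is deterministic given
#'   the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cores = 55L,
                       compartment_prob = c(tumour = 0.85, stroma = 0.60,
                                            immune = 0.35),
                       n_genes = 2000L,
                       n_cell_types = 8L,
                       libsize_meanlog = log(2e5), libsize_sdlog = 0.35,
                       nb_dispersion = 0.2,
                       n_active_ligands = 10L, active_target_r = 0.6,
                       n_targets_per_active = 20L,
                       active_pair = c("stroma", "tumour"),
                       n_null_ligands = 40L, n_targets_per_null = 10L,
                       n_de_genes_per_compartment = 30L, de_lfc = 2,
                       n_subtype_genes = 200L, subtype_r = 0.6,
                       qc_fail = c(min_raw_reads = 1L, min_saturation = 1L,
                                   min_pct_aligned = 1L,
                                   min_genes_detected_frac = 1L),
                       seed) {
  if (missing(seed)) abort_validation("sim_config requires an explicit seed")
  stopifnot(n_cores >= 3L, all(compartment_prob >= 0 & compartment_prob <= 1),
            all(sort(names(compartment_prob)) == sort(COMPARTMENTS)),
            n_cell_types >= 2L, n_cell_types <= 8L,
            nb_dispersion >= 0,
            active_target_r > -1, active_target_r < 1,
            subtype_r > -1, subtype_r < 1,
            all(active_pair %in% COMPARTMENTS), length(active_pair) == 2L)
  n_ligands <- n_active_ligands + n_null_ligands
  need <- n_ligands + n_active_ligands * n_targets_per_active + 300L +
    n_subtype_genes + 3L * n_de_genes_per_compartment
  if (n_genes < need + 50L)
    abort_validation("n_genes = ", n_genes, " too small for the planted ",
                     "structure; need at least ", need + 50L)
  structure(as.list(environment()), class = "sim_config")
}

CELL_TYPE_NAMES <- c("malignant", "urothelial", "MyoCAF", "MatrixCAF",
                     "B_cell", "T_cell", "macrophage", "endothelial")

compartment_alpha <- function(cell_types) {
  # Dirichlet concentration per compartment; qualitative composition only:
  # tumour malignant/urothelial-dominated, stroma MyoCAF-led with B cells,
  # immune B-cell/macrophage-led.
  base <- rep(0.3, length(cell_types)); names(base) <- cell_types
  a <- list(tumour = base, stroma = base, immune = base)
  set_if <- function(v, nm, val) { v[intersect(nm, names(v))] <- val; v }
  a$tumour <- set_if(a$tumour, "malignant", 20)
  a$tumour <- set_if(a$tumour, "urothelial", 5)
  a$stroma <- set_if(a$stroma, "MyoCAF", 15)
  a$stroma <- set_if(a$stroma, "MatrixCAF", 4)
  a$stroma <- set_if(a$stroma, "B_cell", 3)
  a$immune <- set_if(a$immune, "B_cell", 12)
  a$immune <- set_if(a$immune, "macrophage", 8)
  a$immune <- set_if(a$immune, "malignant", 3)
  a
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

SUBTYPE_LABELS <- c("Basal", "LumP", "LumNS", "LumU", "Stroma_rich", "NE_like")

#' Generate a complete synthetic dataset with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` ([count_matrix()]), `annot`
#'   ([roi_annotation()]), `profiles` ([cell_profile_matrix()]), `prior`
#'   ([ligand_target_prior()]), `network` ([signalling_network()]),
#'   `centroids` ([centroid_matrix()]) and `truth` (planted proportions,
#'   active/null ligand sets with coupling, per-compartment DE genes,
#'   subtype labels, QC failures per ROI).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ct <- CELL_TYPE_NAMES[seq_len(cfg$n_cell_types)]

  ## --- gene universe partition -------------------------------------------
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  lig_active <- sprintf("LIGA%02d", seq_len(cfg$n_active_ligands))
  lig_null <- sprintf("LIGN%02d", seq_len(cfg$n_null_ligands))
  pos <- 0L
  grab <- function(n) { out <- genes[pos + seq_len(n)]; pos <<- pos + n; out }
  active_targets <- lapply(seq_len(cfg$n_active_ligands),
                           function(i) grab(cfg$n_targets_per_active))
  names(active_targets) <- lig_active
  decoy_pool <- grab(300L)
  null_targets <- lapply(seq_len(cfg$n_null_ligands),
                         function(i) sample(decoy_pool, cfg$n_targets_per_null))
  names(null_targets) <- lig_null
  subtype_genes <- grab(cfg$n_subtype_genes)
  de_genes <- list(tumour = grab(cfg$n_de_genes_per_compartment),
                   stroma = grab(cfg$n_de_genes_per_compartment),
                   immune = grab(cfg$n_de_genes_per_compartment))
  profile_genes <- genes[(pos + 1L):cfg$n_genes]
  all_genes <- c(genes, lig_active, lig_null)

  ## --- cell profiles ------------------------------------------------------
  # profile-informative genes: log-normal per (gene, cell type); genes with a
  # planted non-compositional role get flat profiles so they never act as
  # deconvolution signatures.
  P <- matrix(exp(stats::rnorm(length(all_genes) * length(ct), 2.0, 1.0)),
              length(all_genes), length(ct), dimnames = list(all_genes, ct))
  flat <- setdiff(all_genes, profile_genes)
  P[flat, ] <- exp(2.0)  # constant across cell types
  profiles <- cell_profile_matrix(P)

  ## --- cores, donors, ROIs ------------------------------------------------
  cores <- sprintf("C%02d", seq_len(cfg$n_cores))
  donors <- sprintf("D%02d", ceiling(seq_len(cfg$n_cores) / 2))
  pr <- cfg$compartment_prob[COMPARTMENTS]
  present <- matrix(stats::runif(cfg$n_cores * 3) < rep(pr, each = cfg$n_cores),
                    cfg$n_cores, 3, dimnames = list(cores, COMPARTMENTS))
  empty <- rowSums(present) == 0L
  present[empty, "tumour"] <- TRUE  # every core contributes >= 1 ROI
  roi <- do.call(rbind, lapply(seq_along(cores), function(i) {
    comp <- COMPARTMENTS[present[i, ]]
    if (length(comp) == 0L) return(NULL)
    data.frame(roi_id = paste0(cores[i], "_", comp), core_id = cores[i],
               donor_id = donors[i], compartment = comp,
               stringsAsFactors = FALSE)
  }))
  n_roi <- nrow(roi)

  ## --- per-ROI composition and base means ---------------------------------
  alpha <- compartment_alpha(ct)
  props <- t(vapply(roi$compartment, function(cp) rdirichlet1(alpha[[cp]]),
                    numeric(length(ct))))
  dimnames(props) <- list(roi$roi_id, ct)
  mu <- unclass(P) %*% t(props)  # gene x ROI linear means

  ## --- planted compartment DE markers -------------------------------------
  for (cp in COMPARTMENTS) {
    in_cp <- roi$compartment == cp
    mu[de_genes[[cp]], in_cp] <- mu[de_genes[[cp]], in_cp] * 2^cfg$de_lfc
  }

  ## --- planted ligand couplings -------------------------------------------
  tau <- 1
  coupling <- cfg$active_target_r / sqrt(1 - cfg$active_target_r^2)
  z_active <- matrix(stats::rnorm(cfg$n_cores * cfg$n_active_ligands),
                     cfg$n_cores, cfg$n_active_ligands,
                     dimnames = list(cores, lig_active))
  z_null <- matrix(stats::rnorm(cfg$n_cores * cfg$n_null_ligands),
                   cfg$n_cores, cfg$n_null_ligands,
                   dimnames = list(cores, lig_null))
  sender <- cfg$active_pair[1L]; receiver <- cfg$active_pair[2L]
  core_of <- roi$core_id
  for (lg in lig_active) {
    s_rois <- roi$roi_id[roi$compartment == sender]
    mu[lg, s_rois] <- mu[lg, s_rois] * 2^z_active[core_of[match(s_rois, roi$roi_id)], lg]
    r_rois <- roi$roi_id[roi$compartment == receiver]
    zc <- z_active[core_of[match(r_rois, roi$roi_id)], lg]
    for (tg in active_targets[[lg]]) {
      eps <- stats::rnorm(length(zc))
      mu[tg, r_rois] <- mu[tg, r_rois] * 2^(coupling * zc + tau * eps)
    }
  }
  for (lg in lig_null) {
    # core-level variation in every compartment, no target coupling
    mu[lg, ] <- mu[lg, ] * 2^z_null[core_of, lg]
  }

  ## --- planted subtype signatures ------------------------------------------
  centroids_log2 <- matrix(stats::rnorm(cfg$n_subtype_genes *
                                          length(SUBTYPE_LABELS)),
                           cfg$n_subtype_genes, length(SUBTYPE_LABELS),
                           dimnames = list(subtype_genes, SUBTYPE_LABELS))
  a_sub <- cfg$subtype_r / sqrt(1 - cfg$subtype_r^2)
  # label frequencies echo the cohort: tumour ROIs a basal/luminal mix with
  # an unassigned remainder; most stroma ROIs stroma-rich; some immune basal.
  pick_label <- function(cp) {
    if (cp == "tumour")
      sample(c(SUBTYPE_LABELS, "none"), 1L,
             prob = c(.30, .24, .12, .10, .02, 0, .22))
    else if (cp == "stroma")
      sample(c("Stroma_rich", "none"), 1L, prob = c(.60, .40))
    else sample(c("Basal", "none"), 1L, prob = c(.40, .60))
  }
  true_subtype <- vapply(roi$compartment, pick_label, "")
  names(true_subtype) <- roi$roi_id
  for (j in seq_len(n_roi)) {
    lab <- true_subtype[j]
    if (lab == "none") next
    eps <- stats::rnorm(cfg$n_subtype_genes)
    mu[subtype_genes, j] <- mu[subtype_genes, j] *
      2^(a_sub * centroids_log2[, lab] + eps)
  }

  ## --- library sizes and counts --------------------------------------------
  lib <- stats::rlnorm(n_roi, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu_scaled <- sweep(mu, 2L, lib / colSums(mu), `*`)
  counts <- matrix(
    if (cfg$nb_dispersion > 0)
      stats::rnbinom(length(mu_scaled), mu = mu_scaled,
                     size = 1 / cfg$nb_dispersion)
    else stats::rpois(length(mu_scaled), mu_scaled),
    nrow(mu_scaled), ncol(mu_scaled), dimnames = dimnames(mu_scaled))

  ## --- QC metadata and planted failures ------------------------------------
  annot <- data.frame(
    roi, raw_reads = round(lib),
    saturation = stats::runif(n_roi, 60, 95),
    pct_aligned = stats::runif(n_roi, 85, 99),
    pct_trimmed = stats::runif(n_roi, 85, 99),
    pct_stitched = stats::runif(n_roi, 85, 99),
    stringsAsFactors = FALSE)
  qc_fail <- cfg$qc_fail
  if (sum(qc_fail) > n_roi)
    abort_validation("more planted QC failures (", sum(qc_fail),
                     ") than ROIs (", n_roi, ")")
  victims <- sample(roi$roi_id, sum(qc_fail))
  truth_qc <- character(0)
  vi <- 0L
  for (rule in names(qc_fail)) {
    for (b in seq_len(qc_fail[[rule]])) {
      vi <- vi + 1L
      id <- victims[vi]
      row <- match(id, annot$roi_id)
      switch(rule,
        min_raw_reads = { annot$raw_reads[row] <- 500 },
        min_saturation = { annot$saturation[row] <- 30 },
        min_pct_aligned = { annot$pct_aligned[row] <- 60 },
        min_pct_trimmed = { annot$pct_trimmed[row] <- 60 },
        min_pct_stitched = { annot$pct_stitched[row] <- 60 },
        min_genes_detected_frac = {
          keep_on <- sample(nrow(counts), ceiling(0.05 * nrow(counts)))
          off <- setdiff(seq_len(nrow(counts)), keep_on)
          counts[off, id] <- 0
        },
        abort_validation("unknown QC rule in qc_fail: ", rule))
      truth_qc[id] <- rule
    }
  }

  ## --- prior and network ----------------------------------------------------
  prior <- do.call(rbind, c(
    lapply(lig_active, function(lg)
      data.frame(ligand = lg, target = active_targets[[lg]],
                 weight = stats::runif(cfg$n_targets_per_active, 0.5, 1),
                 stringsAsFactors = FALSE)),
    lapply(lig_null, function(lg)
      data.frame(ligand = lg, target = null_targets[[lg]],
                 weight = stats::runif(cfg$n_targets_per_null, 0.5, 1),
                 stringsAsFactors = FALSE))))
  prior <- ligand_target_prior(prior)

  net <- do.call(rbind, lapply(seq_along(lig_active), function(i) {
    lg <- lig_active[i]
    rec <- paste0("REC", i); kin <- paste0("KIN", i); tf <- paste0("TF", i)
    rbind(
      data.frame(source = lg, target = rec, weight = 0.9,
                 layer = "ligand_receptor", stringsAsFactors = FALSE),
      data.frame(source = rec, target = kin, weight = 0.8,
                 layer = "signalling", stringsAsFactors = FALSE),
      data.frame(source = kin, target = tf, weight = 0.8,
                 layer = "signalling", stringsAsFactors = FALSE),
      data.frame(source = tf, target = active_targets[[lg]][1:3], weight = 0.7,
                 layer = "gene_regulatory", stringsAsFactors = FALSE))
  }))
  network <- signalling_network(net)

  list(counts = count_matrix(counts),
       annot = roi_annotation(annot),
       profiles = profiles,
       prior = prior,
       network = network,
       centroids = centroid_matrix(centroids_log2),
       truth = list(
         proportions = props,
         active_ligands = lig_active,
         null_ligands = lig_null,
         active_targets = active_targets,
         coupling = coupling,
         population_r = cfg$active_target_r,
         active_pair = cfg$active_pair,
         de_genes = de_genes,
         de_lfc = cfg$de_lfc,
         subtype = true_subtype,
         subtype_genes = subtype_genes,
         profile_genes = profile_genes,
         qc_failures = truth_qc,
         library_sizes = stats::setNames(lib, roi$roi_id)))
}

#' Miniature deterministic fixture
#'
#' A hand-checkable dataset (50 genes, 12 ROIs: 4 cores x 3 compartments)
#' built without any random draws. Core C04's three ROIs are planted to fail
#' one QC rule each (raw reads, saturation, gene-detection fraction), so QC
#' keeps 9 ROIs across cores C01-C03. One ligand, `LIG1`, is planted with
#' deterministic monotone coupling to its five targets `T01`-`T05` from
#' stroma to tumour, making its activity close to 1.
#'
#' @return Same shape as [generate_dataset()] (minus profiles/centroids):
#'   list with `counts`, `annot`, `prior`, `truth`.
#' @export
small_fixture <- function() {
  bg <- sprintf("B%02d", 1:44)
  genes <- c(bg, "LIG1", sprintf("T%02d", 1:5))
  cores <- sprintf("C%02d", 1:4)
  roi <- expand.grid(compartment = COMPARTMENTS, core_id = cores,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  roi$roi_id <- paste0(roi$core_id, "_", roi$compartment)
  roi$donor_id <- ifelse(roi$core_id %in% c("C01", "C02"), "D01", "D02")

  counts <- outer(seq_along(genes), seq_len(nrow(roi)),
                  function(i, j) (i * 7 + j * 13) %% 20 + 1)
  dimnames(counts) <- list(genes, roi$roi_id)
  for (c_i in 1:4) {
    s_id <- paste0(cores[c_i], "_stroma"); t_id <- paste0(cores[c_i], "_tumour")
    counts["LIG1", s_id] <- 10 * c_i
    for (k in 1:5) counts[paste0("T", sprintf("%02d", k)), t_id] <- 5 * c_i + k
  }

  annot <- data.frame(roi[c("roi_id", "core_id", "donor_id", "compartment")],
                      raw_reads = 150000, saturation = 85, pct_aligned = 95,
                      pct_trimmed = 95, pct_stitched = 95,
                      stringsAsFactors = FALSE)
  annot$raw_reads[annot$roi_id == "C04_tumour"] <- 500
  annot$saturation[annot$roi_id == "C04_stroma"] <- 30
  counts[-(1:2), "C04_immune"] <- 0  # 2/50 = 4% genes detected

  prior <- ligand_target_prior(data.frame(
    ligand = "LIG1", target = sprintf("T%02d", 1:5),
    weight = seq(1, 0.6, by = -0.1), stringsAsFactors = FALSE))

  list(counts = count_matrix(counts), annot = roi_annotation(annot),
       prior = prior,
       truth = list(
         qc_failures = c(C04_tumour = "min_raw_reads",
                         C04_stroma = "min_saturation",
                         C04_immune = "min_genes_detected_frac"),
         active_ligands = "LIG1",
         active_targets = list(LIG1 = sprintf("T%02d", 1:5)),
         active_pair = c("stroma", "tumour")))
}
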