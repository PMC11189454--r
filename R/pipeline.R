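# End-to-end orchestration: qc -> normalise -> log2 -> DE -> deconvolution
# -> ligand activity per compartment pair -> origin correlation -> subtyping
# -> path inference. Every stage output is a TSV; the manifest records row
# counts and parameter echoes so dropped data is always accounted for.

DEFAULT_PAIRS <- list(c("stroma", "tumour"), c("stroma", "stroma"),
                      c("tumour", "stroma"), c("tumour", "tumour"),
                      c("immune", "tumour"))

#' Pipeline run configuration
#'
#' @param counts,annot,prior paths to TSV inputs, or in-memory objects of the
#'   corresponding types.
#' @param profiles,centroids,network optional inputs; the matching stages are
#'   skipped when absent.
#' @param out_dir output directory (created if missing).
#' @param qc a [qc_thresholds()].
#' @param crosstalk a [crosstalk_config()].
#' @param pairs list of c(sender, receiver) compartment pairs to score;
#'   default stroma->tumour, stroma->stroma, tumour->stroma, tumour->tumour,
#'   immune->tumour.
#' @param contrasts character vector of DE contrasts `"<compartment>:rest"`.
#' @param seed integer seed echoed into the manifest (the deterministic
#'   stages do not consume randomness).
#' @return A `run_config` list.
#' @export
run_config <- function(counts, annot, prior, out_dir,
                       profiles = NULL, centroids = NULL, network = NULL,
                       qc = qc_thresholds(), crosstalk = crosstalk_config(),
                       pairs = DEFAULT_PAIRS,
                       contrasts = c("tumour:rest", "stroma:rest",
                                     "immune:rest"),
                       seed = 1L) {
  for (p in pairs)
    if (!all(p %in% COMPARTMENTS))
      abort_validation("pair outside the compartment set: ",
                       paste(p, collapse = "->"))
  structure(list(counts = counts, annot = annot, prior = prior,
                 profiles = profiles, centroids = centroids,
                 network = network, out_dir = out_dir, qc = qc,
                 crosstalk = crosstalk, pairs = pairs,
                 contrasts = contrasts, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' JSON fields mirror [run_config()] arguments; input paths are resolved
#' relative to the JSON file's directory. `qc` and `crosstalk` are optional
#' objects of threshold overrides.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else
    if (startsWith(p, "/")) p else file.path(base, p)
  qc <- do.call(qc_thresholds, as.list(j$qc))
  ck <- do.call(crosstalk_config, as.list(j$crosstalk))
  pairs <- if (is.null(j$pairs)) DEFAULT_PAIRS else
    lapply(seq_len(nrow(j$pairs)), function(i) unlist(j$pairs[i, ]))
  run_config(counts = resolve(j$counts), annot = resolve(j$annot),
             prior = resolve(j$prior), profiles = resolve(j$profiles),
             centroids = resolve(j$centroids), network = resolve(j$network),
             out_dir = resolve(j$out_dir), qc = qc, crosstalk = ck,
             pairs = pairs,
             contrasts = if (is.null(j$contrasts))
               c("tumour:rest", "stroma:rest", "immune:rest") else j$contrasts,
             seed = if (is.null(j$seed)) 1L else j$seed)
}

load_input <- function(x, reader, class_wanted) {
  if (is.null(x)) return(NULL)
  if (inherits(x, class_wanted)) return(x)
  if (is.character(x) && length(x) == 1L) return(reader(x))
  abort_validation("input must be a path or a ", class_wanted)
}

#' Run the full analysis
#'
#' Executes QC, Q3 normalisation, log2 transform, differential expression per
#' contrast, deconvolution (if profiles given), ligand activity for each
#' configured compartment pair, ligand-origin correlation, subtyping (if
#' centroids given) and path inference for the top active ligands (if a
#' network is given). All outputs are TSVs under `cfg$out_dir`; the manifest
#' (also written as `manifest.json`) records per-stage counts. A stage
#' failure aborts with the stage name; a `FAILED` marker file is left.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly a list.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  unlink(log_path); unlink(file.path(cfg$out_dir, "FAILED"))

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("roicrosstalk")),
                   seed = cfg$seed,
                   parameters = list(qc = unclass(cfg$qc),
                                     crosstalk = unclass(cfg$crosstalk)))

  counts <- stage("load_counts", function()
    load_input(cfg$counts, read_count_matrix, "count_matrix"))
  annot <- stage("load_annot", function()
    load_input(cfg$annot, read_annotation, "roi_annotation"))
  prior <- stage("load_prior", function()
    load_input(cfg$prior, read_prior, "ligand_target_prior"))
  profiles <- load_input(cfg$profiles, read_profiles, "cell_profile_matrix")
  centroids <- load_input(cfg$centroids, read_centroids, "centroid_matrix")
  network <- load_input(cfg$network, read_network, "signalling_network")

  ## QC
  qr <- stage("filter_rois", function() filter_rois(counts, annot, cfg$qc))
  for (id in qr$report$removed_roi_ids)
    logf("ROI_EXCLUDED\t", id, "\t",
         paste(qr$report$failed_rules[[id]], collapse = ";"))
  gr <- stage("filter_genes", function()
    filter_genes(qr$counts, cfg$qc$gene_detection_frac, cfg$qc$detect_min_count))
  for (id in gr$report$removed_gene_ids) logf("GENE_EXCLUDED\t", id)
  manifest$n_rois_in <- ncol(counts)
  manifest$n_rois_kept <- ncol(qr$counts)
  manifest$n_genes_in <- nrow(counts)
  manifest$n_genes_kept <- nrow(gr$counts)
  write_count_matrix(gr$counts, file.path(cfg$out_dir, "counts_qc.tsv"))
  utils::write.table(qr$report$roi, file.path(cfg$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## normalisation
  norm <- stage("q3_normalize", function() q3_normalize(gr$counts))
  lg <- stage("log2_transform", function() log2_transform(norm))
  write_expression_matrix(norm, file.path(cfg$out_dir, "norm.tsv"))
  write_expression_matrix(lg, file.path(cfg$out_dir, "log2.tsv"))
  annot_kept <- qr$annot

  ## differential expression
  de_counts <- list()
  for (ctr in cfg$contrasts) {
    cp <- strsplit(ctr, ":", fixed = TRUE)[[1L]][1L]
    ga <- annot_kept$roi_id[annot_kept$compartment == cp]
    gb <- setdiff(annot_kept$roi_id, ga)
    if (length(ga) < 2L || length(gb) < 2L) {
      logf("DE_SKIPPED\t", ctr, "\tgroup too small")
      next
    }
    de <- stage(paste0("de_", cp), function() moderated_t(lg, ga, gb))
    utils::write.table(de, file.path(cfg$out_dir, paste0("de_", cp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de_counts[[ctr]] <- sum(de$adj_p_value < 0.05)
  }
  manifest$n_de_significant <- de_counts

  ## deconvolution
  proportions <- NULL
  if (!is.null(profiles)) {
    dv <- stage("deconv", function() estimate_proportions(norm, profiles))
    proportions <- dv$proportions
    pt <- data.frame(roi_id = rownames(proportions), proportions,
                     resid_norm = dv$resid_norm, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(pt, file.path(cfg$out_dir, "proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ligand activity per compartment pair
  act_all <- list(); pair_counts <- list(); active_counts <- list()
  prior_r <- stage("restrict_prior", function()
    restrict_prior(prior, rownames(lg), cfg$crosstalk))
  for (p in cfg$pairs) {
    key <- paste0(p[1L], "_to_", p[2L])
    pr <- tryCatch(build_pairs(annot_kept, lg, p[1L], p[2L],
                               cfg$crosstalk$min_pairs),
                   roicrosstalk_validation_error = function(e) {
                     logf("PAIR_SKIPPED\t", key, "\t", conditionMessage(e))
                     NULL
                   })
    if (is.null(pr)) next
    for (sc in pr$skipped_cores) logf("CORE_SKIPPED\t", key, "\t", sc)
    res <- stage(paste0("activity_", key), function()
      ligand_activity(pr, prior_r, cfg$crosstalk))
    for (ne in res$activity$ligand[!res$activity$evaluable])
      logf("LIGAND_NOT_EVALUABLE\t", key, "\t", ne)
    utils::write.table(res$activity,
                       file.path(cfg$out_dir, paste0("activity_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$target_r))
      utils::write.table(res$target_r,
                         file.path(cfg$out_dir, paste0("edges_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    act_all[[key]] <- res$activity
    pair_counts[[key]] <- length(pr$core_ids)
    active_counts[[key]] <- sum(res$activity$active)
  }
  manifest$n_pairs <- pair_counts
  manifest$n_active_ligands <- active_counts

  ## ligand -> cell-type origin
  if (!is.null(proportions) && length(act_all) > 0L) {
    active_ligs <- unique(unlist(lapply(act_all, function(a)
      a$ligand[a$active])))
    if (length(active_ligs) > 0L) {
      oc <- stage("origin_correlation", function()
        correlate_ligands_with_cells(lg, proportions, active_ligs))
      utils::write.table(oc$edges, file.path(cfg$out_dir, "ligand_origin.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$n_origin_edges <- nrow(oc$edges)
    }
  }

  ## subtyping
  if (!is.null(centroids)) {
    st <- stage("subtype", function() classify_subtypes(lg, centroids))
    utils::write.table(st, file.path(cfg$out_dir, "subtypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$subtype_counts <- as.list(table(st$label))
  }

  ## path inference for top active ligands
  if (!is.null(network) && length(act_all) > 0L) {
    paths <- list()
    for (key in names(act_all)) {
      a <- act_all[[key]]
      top <- utils::head(a$ligand[a$active][order(-a$activity[a$active])], 3L)
      for (lgd in top) {
        # try the ligand's highest-weight targets until one is reachable
        for (tgt in utils::head(prior_r$target[prior_r$ligand == lgd], 10L)) {
          pth <- tryCatch(infer_path(network, lgd, tgt),
                          roicrosstalk_validation_error = function(e) NULL)
          if (!is.null(pth) && pth$found) {
            paths[[length(paths) + 1L]] <- data.frame(
              pair = key, ligand = lgd, target = tgt,
              path = paste(pth$nodes, collapse = "->"), score = pth$score,
              stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    if (length(paths) > 0L)
      utils::write.table(do.call(rbind, paths),
                         file.path(cfg$out_dir, "paths.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$n_paths <- length(paths)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
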