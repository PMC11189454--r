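# Ligand-to-target path inference over the layered weighted network.
#
# The optimal path maximises the product of edge weights among paths of at
# most max_len edges whose FIRST edge is a ligand_receptor edge (a ligand
# must engage a receptor before intracellular signalling). Equivalent to a
# shortest path under cost -log(weight); implemented as dynamic programming
# over path length, which bounds max_len naturally and makes the tie-breaks
# (fewer edges, then lexicographic node sequence) deterministic. Weights lie
# in (0, 1], so cycles never improve a product and the optimum is a simple
# path.

#' Infer the most probable ligand-to-target signalling path
#'
#' @param network a [signalling_network()].
#' @param ligand,target gene symbols; the ligand must have at least one
#'   outgoing `ligand_receptor` edge.
#' @param max_len maximum number of edges (default 6).
#' @return A `signalling_path`: list with `found`, `nodes` (ordered, ligand
#'   first), `weights` (per edge), `score` (product), `n_edges`; or
#'   `found = FALSE` when no admissible path exists within `max_len`.
#' @export
infer_path <- function(network, ligand, target, max_len = 6L) {
  stopifnot(inherits(network, "signalling_network"))
  nodes <- sort(unique(c(network$source, network$target)))
  if (!target %in% nodes)
    abort_validation("target '", target, "' not present in network")
  first <- network[network$layer == "ligand_receptor" &
                     network$source == ligand, , drop = FALSE]
  if (nrow(first) == 0L)
    abort_validation("ligand '", ligand,
                     "' has no outgoing ligand_receptor edge")

  # best[[v]]: list(score, path) of the best admissible path ligand -> v
  # with exactly the current number of edges; `opt` keeps the best overall
  # at <= k edges with deterministic tie-breaking.
  better <- function(a, b) {
    # TRUE if a beats b
    if (is.null(b)) return(TRUE)
    if (a$score != b$score) return(a$score > b$score)
    if (length(a$path) != length(b$path))
      return(length(a$path) < length(b$path))
    paste(a$path, collapse = "\r") < paste(b$path, collapse = "\r")
  }

  frontier <- list()
  for (i in seq_len(nrow(first))) {
    cand <- list(score = first$weight[i],
                 path = c(ligand, first$target[i]))
    v <- first$target[i]
    if (better(cand, frontier[[v]][["best"]]))
      frontier[[v]] <- list(best = cand)
  }
  frontier <- lapply(frontier, `[[`, "best")
  opt <- frontier[[target]]

  later <- network[network$layer != "ligand_receptor", , drop = FALSE]
  k <- 1L
  while (k < max_len && length(frontier) > 0L) {
    k <- k + 1L
    nxt <- list()
    for (v in names(frontier)) {
      cur <- frontier[[v]]
      out_e <- later[later$source == v, , drop = FALSE]
      for (i in seq_len(nrow(out_e))) {
        u <- out_e$target[i]
        cand <- list(score = cur$score * out_e$weight[i],
                     path = c(cur$path, u))
        if (better(cand, nxt[[u]])) nxt[[u]] <- cand
      }
    }
    frontier <- nxt
    if (!is.null(frontier[[target]]) && better(frontier[[target]], opt))
      opt <- frontier[[target]]
  }

  if (is.null(opt))
    return(structure(list(found = FALSE, nodes = character(0),
                          weights = numeric(0), score = NA_real_,
                          n_edges = 0L, ligand = ligand, target = target),
                     class = "signalling_path"))
  path <- opt$path
  w <- numeric(length(path) - 1L)
  for (i in seq_along(w)) {
    hit <- network[network$source == path[i] & network$target == path[i + 1L], ]
    w[i] <- max(hit$weight)
  }
  structure(list(found = TRUE, nodes = path, weights = w, score = opt$score,
                 n_edges = length(w), ligand = ligand, target = target),
            class = "signalling_path")
}
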