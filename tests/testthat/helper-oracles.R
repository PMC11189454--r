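# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: scalar arithmetic, exhaustive enumeration, closed forms.

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# linear-interpolation 75th percentile (quantile type 7), written out
oracle_q3 <- function(v) {
  s <- sort(v)
  h <- (length(s) - 1) * 0.75 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_q3_normalize <- function(m) {
  q3 <- apply(m, 2, oracle_q3)
  gm <- exp(mean(log(q3)))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- m[, j] * gm / q3[j]
  out
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
}

# exhaustive enumeration of admissible simple paths (first edge in the
# ligand_receptor layer) of <= max_len edges; returns the best score with
# the package's tie-break order (score, fewer edges, lexicographic nodes)
oracle_best_path <- function(net, ligand, target, max_len = 6L) {
  best <- NULL
  consider <- function(path, score) {
    cand <- list(score = score, path = path)
    if (is.null(best)) { best <<- cand; return() }
    if (cand$score > best$score ||
        (cand$score == best$score && length(cand$path) < length(best$path)) ||
        (cand$score == best$score && length(cand$path) == length(best$path) &&
         paste(cand$path, collapse = "\r") < paste(best$path, collapse = "\r")))
      best <<- cand
  }
  recurse <- function(node, path, score, depth) {
    if (node == target && depth > 0) consider(path, score)
    if (depth >= max_len) return()
    layers <- if (depth == 0) "ligand_receptor" else
      c("signalling", "gene_regulatory")
    e <- net[net$source == node & net$layer %in% layers, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (e$target[i] %in% path) next
      recurse(e$target[i], c(path, e$target[i]), score * e$weight[i],
              depth + 1L)
    }
  }
  recurse(ligand, ligand, 1, 0L)
  best
}

# random layered network over <= 6 nodes with an admissible query
random_network <- function(seed) {
  set.seed(seed)
  mids <- c("A", "B", "C", "D")
  edges <- list()
  edges[[1]] <- data.frame(source = "L", target = sample(mids, 2),
                           weight = round(runif(2, 0.1, 1), 3),
                           layer = "ligand_receptor",
                           stringsAsFactors = FALSE)
  all_nodes <- c(mids, "T")
  for (s in mids) {
    outs <- sample(setdiff(all_nodes, s), sample(1:3, 1))
    edges[[length(edges) + 1]] <- data.frame(
      source = s, target = outs, weight = round(runif(length(outs), 0.1, 1), 3),
      layer = sample(c("signalling", "gene_regulatory"), length(outs),
                     replace = TRUE),
      stringsAsFactors = FALSE)
  }
  df <- unique(do.call(rbind, edges))
  df <- df[!duplicated(df[c("source", "target")]), ]
  signalling_network(df)
}

# exhaustive hypergeometric tail by enumerating all draws of size n from the
# universe (universe size <= 15)
oracle_hyper_tail <- function(gene_list, gene_set, universe) {
  n <- length(gene_list)
  k_obs <- length(intersect(gene_list, gene_set))
  combs <- utils::combn(universe, n)
  hits <- sum(apply(combs, 2, function(dr)
    length(intersect(dr, gene_set)) >= k_obs))
  hits / ncol(combs)
}

# minimal valid annotation builder
make_annot <- function(roi_id, compartment, core_id = roi_id,
                       donor_id = core_id, raw_reads = 1e5, saturation = 85,
                       pct_aligned = 95, pct_trimmed = 95, pct_stitched = 95) {
  roi_annotation(data.frame(roi_id = roi_id, core_id = core_id,
                            donor_id = donor_id, compartment = compartment,
                            raw_reads = raw_reads, saturation = saturation,
                            pct_aligned = pct_aligned,
                            pct_trimmed = pct_trimmed,
                            pct_stitched = pct_stitched,
                            stringsAsFactors = FALSE))
}

make_counts <- function(nr, nc, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, 50), nr, nc,
              dimnames = list(sprintf("g%03d", seq_len(nr)),
                              sprintf("roi%02d", seq_len(nc))))
  count_matrix(m)
}
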