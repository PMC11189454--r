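as_log2 <- function(m) expression_matrix(m, "log2")

# 3 cores x (tumour, stroma) single-ROI expression over a few genes
simple_pair_setup <- function(extra_core = TRUE) {
  genes <- c("LIG", "T1", "T2", "G1")
  rois <- c("C1_t", "C1_s", "C2_t", "C2_s", "C3_t", "C3_s",
            if (extra_core) "C4_t")
  set.seed(41)
  m <- matrix(rnorm(length(genes) * length(rois), 6, 1), length(genes),
              length(rois), dimnames = list(genes, rois))
  comp <- ifelse(grepl("_t$", rois), "tumour", "stroma")
  core <- sub("_.$", "", rois)
  list(expr = as_log2(m), annot = make_annot(rois, comp, core_id = core))
}

test_that("build_pairs emits one pair per complete core and logs gaps", {
  s <- simple_pair_setup(extra_core = TRUE)  # C4 has tumour but no stroma
  pr <- build_pairs(s$annot, s$expr, "stroma", "tumour")
  expect_equal(pr$core_ids, c("C1", "C2", "C3"))
  expect_equal(pr$skipped_cores, "C4")
  expect_equal(pr$sender_profiles[, "C2"], unclass(s$expr)[, "C2_s"])
  expect_equal(pr$receiver_profiles[, "C2"], unclass(s$expr)[, "C2_t"])
})

test_that("multi-ROI compartments are aggregated by arithmetic mean", {
  genes <- c("g", "h")
  m <- matrix(c(2, 1, 4, 3, 5, 2,  6, 1, 7, 2, 8, 3), 2, 6,
              dimnames = list(genes,
                              c("C1_s1", "C1_s2", "C1_t", "C2_s", "C2_t",
                                "C3_both")))
  an <- make_annot(colnames(m),
                   c("stroma", "stroma", "tumour", "stroma", "tumour",
                     "stroma"),
                   core_id = c("C1", "C1", "C1", "C2", "C2", "C3"))
  # C3 lacks tumour: min_pairs = 2 to let the test observe the skip
  pr <- build_pairs(an, as_log2(m), "stroma", "tumour", min_pairs = 2)
  expect_equal(pr$sender_profiles["g", "C1"], mean(c(2, 4)))
  expect_equal(pr$skipped_cores, "C3")
  expect_error(build_pairs(an, as_log2(m), "stroma", "tumour", min_pairs = 3),
               "2 stroma->tumour core pairs")
})

test_that("sender = receiver yields identical profiles by construction", {
  s <- simple_pair_setup(FALSE)
  pr <- build_pairs(s$annot, s$expr, "stroma", "stroma")
  expect_identical(pr$sender_profiles, pr$receiver_profiles)
})

test_that("restrict_prior keeps in-dataset pairs and top-k by weight", {
  prior <- ligand_target_prior(data.frame(
    ligand = "L", target = c("A", "B", "C"), weight = c(0.9, 0.5, 0.7)))
  cfg <- crosstalk_config(min_targets_present = 2,
                          top_k_targets_per_ligand = 200)
  rp <- restrict_prior(prior, c("L", "A", "B"), cfg)
  expect_setequal(rp$target, c("A", "B"))

  # ligand with fewer surviving targets than min_targets_present is dropped
  prior2 <- ligand_target_prior(data.frame(
    ligand = rep(c("L1", "L2"), c(6, 4)),
    target = c(paste0("a", 1:6), paste0("b", 1:4)),
    weight = runif(10, 0.2, 1)))
  rp2 <- restrict_prior(prior2, c("L1", "L2", paste0("a", 1:6),
                                  paste0("b", 1:4)),
                        crosstalk_config(min_targets_present = 5))
  expect_setequal(unique(rp2$ligand), "L1")
  expect_error(restrict_prior(prior2, "nothing"), "no usable ligand")

  # 300-target ligand, top_k = 200: exactly the 200 highest weights survive
  set.seed(42)
  w <- runif(300)
  prior3 <- ligand_target_prior(data.frame(
    ligand = "L", target = sprintf("t%03d", 1:300), weight = w))
  rp3 <- restrict_prior(prior3, c("L", sprintf("t%03d", 1:300)),
                        crosstalk_config(top_k_targets_per_ligand = 200))
  manual <- sprintf("t%03d", order(-w, sprintf("t%03d", 1:300))[1:200])
  expect_setequal(rp3$target, manual)

  # ties broken by lexicographic target symbol
  prior4 <- ligand_target_prior(data.frame(
    ligand = "L", target = c("z1", "a1", "m1", "b1", "c1", "d1"),
    weight = c(1, 1, 1, 1, 1, 1)))
  rp4 <- restrict_prior(prior4, c("L", "z1", "a1", "m1", "b1", "c1", "d1"),
                        crosstalk_config(top_k_targets_per_ligand = 5,
                                         min_targets_present = 2))
  expect_setequal(rp4$target, c("a1", "b1", "c1", "d1", "m1"))
})

test_that("5-pair hand matrix: activity equals the scalar Pearson oracle", {
  sender <- rbind(LIG = c(1, 3, 2, 5, 4))
  receiver <- rbind(T1 = c(2.0, 2.9, 2.5, 4.1, 3.3),
                    T2 = c(1.1, 0.4, 0.9, 0.2, 0.6),
                    T3 = c(7.0, 7.5, 6.9, 8.1, 7.7))
  colnames(sender) <- colnames(receiver) <- paste0("C", 1:5)
  pairs <- structure(list(core_ids = paste0("C", 1:5),
                          sender_profiles = sender,
                          receiver_profiles = receiver,
                          sender = "stroma", receiver = "tumour",
                          skipped_cores = character(0)),
                     class = "roi_pairing")
  prior <- ligand_target_prior(data.frame(
    ligand = "LIG", target = c("T1", "T2", "T3"), weight = c(1, 1, 1)))
  res <- ligand_activity(pairs, prior,
                         crosstalk_config(min_targets_present = 2))
  manual <- mean(c(oracle_pearson(sender["LIG", ], receiver["T1", ]),
                   oracle_pearson(sender["LIG", ], receiver["T2", ]),
                   oracle_pearson(sender["LIG", ], receiver["T3", ])))
  expect_equal(res$activity$activity, manual, tolerance = 1e-12)
  expect_equal(res$activity$n_targets_used, 3L)
  expect_equal(res$target_r$r[res$target_r$target == "T1"],
               oracle_pearson(sender["LIG", ], receiver["T1", ]),
               tolerance = 1e-12)
})

test_that("perfect coupling gives activity 1; constant sender is flagged", {
  x <- c(1, 4, 2, 6, 3)
  sender <- rbind(LIG = x, FLAT = rep(2, 5))
  receiver <- rbind(T1 = 2 * x + 1, T2 = 0.5 * x - 3, T3 = rep(7, 5))
  colnames(sender) <- colnames(receiver) <- paste0("C", 1:5)
  pairs <- structure(list(core_ids = paste0("C", 1:5),
                          sender_profiles = sender,
                          receiver_profiles = receiver,
                          sender = "stroma", receiver = "tumour",
                          skipped_cores = character(0)),
                     class = "roi_pairing")
  prior <- ligand_target_prior(data.frame(
    ligand = c("LIG", "LIG", "LIG", "FLAT", "FLAT"),
    target = c("T1", "T2", "T3", "T1", "T2"), weight = 1))
  res <- ligand_activity(pairs, prior,
                         crosstalk_config(min_targets_present = 2))
  lig <- res$activity[res$activity$ligand == "LIG", ]
  expect_equal(lig$activity, 1, tolerance = 1e-12)
  expect_true(lig$active)
  expect_equal(lig$n_targets_skipped, 1L)  # constant target T3 skipped
  flat <- res$activity[res$activity$ligand == "FLAT", ]
  expect_false(flat$evaluable)
  expect_false(flat$active)
  expect_true(is.na(flat$activity))
})

test_that("activity is invariant to affine rescaling and pair permutation", {
  set.seed(43)
  G <- 30
  sender <- matrix(rnorm(G * 8, 6, 1), G, 8,
                   dimnames = list(c("LIG", sprintf("t%02d", 1:(G - 1))),
                                   paste0("C", 1:8)))
  receiver <- matrix(rnorm(G * 8, 6, 1), G, 8, dimnames = dimnames(sender))
  prior <- ligand_target_prior(data.frame(
    ligand = "LIG", target = sprintf("t%02d", 1:10), weight = 1))
  mk <- function(s, r, ord = 1:8) structure(
    list(core_ids = paste0("C", 1:8)[ord],
         sender_profiles = s[, ord], receiver_profiles = r[, ord],
         sender = "stroma", receiver = "tumour",
         skipped_cores = character(0)), class = "roi_pairing")
  cfg <- crosstalk_config(min_targets_present = 2)
  base <- ligand_activity(mk(sender, receiver), prior, cfg)$activity$activity
  aff <- ligand_activity(mk(3.7 * sender + 2, 0.2 * receiver - 5), prior,
                         cfg)$activity$activity
  expect_equal(aff, base, tolerance = 1e-12)
  perm <- sample(8)
  shuf <- ligand_activity(mk(sender, receiver, perm), prior,
                          cfg)$activity$activity
  expect_equal(shuf, base, tolerance = 1e-12)
})

test_that("ligand-cell correlation matches a full-matrix oracle", {
  set.seed(44)
  n_roi <- 20
  rois <- sprintf("r%02d", 1:n_roi)
  props <- matrix(runif(n_roi * 3), n_roi, 3,
                  dimnames = list(rois, c("ctA", "ctB", "ctC")))
  props <- props / rowSums(props)
  expr <- matrix(rnorm(5 * n_roi, 6, 1), 5, n_roi,
                 dimnames = list(paste0("L", 1:5), rois))
  expr["L1", ] <- props[, "ctB"]  # identical vector => r = 1
  expr["L2", ] <- -(props[, "ctC"] - mean(props[, "ctC"]))  # r = -1
  res <- correlate_ligands_with_cells(as_log2(expr), props, paste0("L", 1:5))
  expect_true(any(res$edges$ligand == "L1" & res$edges$cell_type == "ctB" &
                    abs(res$edges$r - 1) < 1e-12))
  expect_false(any(res$edges$ligand == "L2" & res$edges$cell_type == "ctC"))

  for (lg in paste0("L", 1:5)) for (ct in colnames(props)) {
    r <- oracle_pearson(expr[lg, ], props[, ct])
    expect_equal(res$all_r[lg, ct], r, tolerance = 1e-12)
    expect_equal(any(res$edges$ligand == lg & res$edges$cell_type == ct),
                 r > 0.2)
  }
  expect_error(correlate_ligands_with_cells(as_log2(expr), props[1:2, ],
                                            "L1"), ">= 3")
})
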