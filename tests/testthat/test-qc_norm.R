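test_that("ROI filter applies each rule with the stated strictness", {
  cm <- make_counts(50, 5)
  an <- make_annot(colnames(cm), rep("tumour", 5),
                   raw_reads = c(999, 1000, 1e5, 1e5, 1e5),
                   saturation = c(85, 50.1, 50, 85, 85),
                   pct_aligned = c(95, 80.1, 95, 80, 95))
  res <- filter_rois(cm, an)
  expect_setequal(res$report$kept_roi_ids, c("roi02", "roi05"))
  expect_equal(res$report$failed_rules$roi01, "min_raw_reads")
  expect_equal(res$report$failed_rules$roi03, "min_saturation")
  expect_equal(res$report$failed_rules$roi04, "min_pct_aligned")
})

test_that("gene-detection ROI rule keeps exactly >= 10% detection", {
  # 50 genes; roi A detects 5 (10%, kept), roi B detects 4 (8%, removed)
  m <- matrix(0, 50, 2, dimnames = list(sprintf("g%02d", 1:50), c("A", "B")))
  m[1:5, "A"] <- 7
  m[1:4, "B"] <- 7
  an <- make_annot(c("A", "B"), c("tumour", "stroma"))
  res <- filter_rois(count_matrix(m), an)
  expect_equal(res$report$kept_roi_ids, "A")
  expect_equal(res$report$failed_rules$B, "min_genes_detected_frac")
})

test_that("fixture QC excludes exactly the planted ROIs, one rule each", {
  fx <- small_fixture()
  res <- filter_rois(fx$counts, fx$annot)
  expect_equal(res$report$n_removed_rois, 3L)
  # independent manual evaluation of every rule on the annotation table
  for (i in seq_len(nrow(fx$annot))) {
    a <- fx$annot[i, ]
    det <- mean(unclass(fx$counts)[, a$roi_id] > 0)
    manual_pass <- a$raw_reads >= 1000 && a$saturation > 50 &&
      a$pct_aligned > 80 && a$pct_trimmed > 80 && a$pct_stitched > 80 &&
      det >= 0.10
    expect_equal(res$report$roi$pass[res$report$roi$roi_id == a$roi_id],
                 manual_pass, info = a$roi_id)
  }
  expect_mapequal(
    lapply(res$report$failed_rules, identity),
    as.list(fx$truth$qc_failures))
})

test_that("ROI filter is order-independent", {
  fx <- small_fixture()
  perm <- c(7, 1, 12, 3, 9, 5, 11, 2, 8, 4, 10, 6)
  cm2 <- count_matrix(unclass(fx$counts)[, perm])
  res1 <- filter_rois(fx$counts, fx$annot)
  res2 <- filter_rois(cm2, fx$annot)
  expect_setequal(res1$report$kept_roi_ids, res2$report$kept_roi_ids)
  expect_equal(res1$report$failed_rules[sort(names(res1$report$failed_rules))],
               res2$report$failed_rules[sort(names(res2$report$failed_rules))])
})

test_that("all ROIs failing is an explicit error", {
  cm <- make_counts(20, 3)
  an <- make_annot(colnames(cm), rep("tumour", 3), raw_reads = 10)
  expect_error(filter_rois(cm, an), "all 3 ROIs fail")
})

test_that("gene filter keeps genes detected in strictly more than frac", {
  # 100 genes x 20 ROIs; plant 25 genes at <= 10% detection (0, 1 or 2 ROIs)
  set.seed(11)
  m <- matrix(rpois(100 * 20, 30) + 1, 100, 20,
              dimnames = list(sprintf("g%03d", 1:100),
                              sprintf("r%02d", 1:20)))
  planted <- sprintf("g%03d", 1:25)
  for (i in 1:25) {
    m[i, ] <- 0
    m[i, seq_len(i %% 3)] <- 5  # detected in 0, 1 or 2 of 20 ROIs (<= 10%)
  }
  res <- filter_genes(count_matrix(m), frac = 0.10)
  # brute-force recount of detection fractions
  manual_keep <- rownames(m)[rowSums(m > 0) / 20 > 0.10]
  expect_setequal(res$report$kept_gene_ids, manual_keep)
  expect_equal(nrow(res$counts), 75L)
  expect_setequal(res$report$removed_gene_ids, planted)

  # boundary cases: 0/20 removed; 3/20 (15%) kept
  expect_true("g001" %in% res$report$removed_gene_ids)  # 0 of 20
  m2 <- m; m2["g001", 1:3] <- 5
  res2 <- filter_genes(count_matrix(m2), frac = 0.10)
  expect_true("g001" %in% res2$report$kept_gene_ids)
})

test_that("gene filter is idempotent and rejects bad fractions", {
  cm <- make_counts(40, 10, seed = 3)
  once <- filter_genes(cm, 0.2)
  twice <- filter_genes(once$counts, 0.2)
  expect_equal(unclass(twice$counts), unclass(once$counts))
  expect_error(filter_genes(cm, 1.2), "\\[0, 1\\]")
})

test_that("Q3 normalisation matches the hand oracle and its invariants", {
  # 4-gene x 2-ROI hand matrix against the spreadsheet-style oracle
  m <- matrix(c(2, 10, 6, 4,
                1, 9, 30, 2), 4, 2,
              dimnames = list(paste0("g", 1:4), c("A", "B")))
  norm <- q3_normalize(count_matrix(m))
  expect_equal(unclass(norm), oracle_q3_normalize(m), tolerance = 1e-12,
               ignore_attr = "scale")

  # two identical ROIs are returned unchanged
  mm <- cbind(A = m[, 1], B = m[, 1])
  rownames(mm) <- paste0("g", 1:4)
  expect_equal(unclass(q3_normalize(count_matrix(mm))), mm,
               tolerance = 1e-12, ignore_attr = "scale")

  # scale invariance: ROI B = 10 x ROI A => identical after normalisation
  ms <- cbind(A = m[, 1], B = 10 * m[, 1])
  rownames(ms) <- paste0("g", 1:4)
  ns <- q3_normalize(count_matrix(ms))
  expect_equal(ns[, "A"], ns[, "B"], tolerance = 1e-12)

  # per-ROI post-normalisation Q3 equal to the common geometric mean
  cm <- make_counts(200, 15, seed = 9)
  nn <- q3_normalize(cm)
  q3s <- apply(unclass(nn), 2, oracle_q3)
  expect_equal(max(abs(q3s / q3s[1] - 1)), 0, tolerance = 1e-9)
})

test_that("Q3 normalisation refuses an all-sparse ROI", {
  m <- matrix(c(5, 6, 7, 8, 0, 0, 0, 0), 4, 2,
              dimnames = list(paste0("g", 1:4), c("ok", "sparse")))
  expect_error(q3_normalize(count_matrix(m)), "sparse")
})

test_that("log2 transform is exact and invertible", {
  ex <- expression_matrix(matrix(c(0, 3, 1, 7), 2, 2,
    dimnames = list(c("g1", "g2"), c("r1", "r2"))), "normalized")
  lg <- log2_transform(ex)
  expect_identical(expr_scale(lg), "log2")
  expect_equal(lg["g1", "r1"], 0)
  expect_equal(lg["g2", "r1"], 2)  # log2(3 + 1)

  set.seed(4)
  rnd <- expression_matrix(matrix(rexp(60, 0.1), 12, 5,
    dimnames = list(sprintf("g%02d", 1:12), sprintf("r%d", 1:5))),
    "normalized")
  inv <- 2^unclass(log2_transform(rnd, offset = 1)) - 1
  expect_equal(inv, unclass(rnd), tolerance = 1e-12, ignore_attr = "scale")

  expect_error(log2_transform(log2_transform(rnd)), "normalized")
})
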