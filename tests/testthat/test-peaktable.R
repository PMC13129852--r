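test_that("peak tables round-trip through disk including the missingness pattern", {
  g <- small_cohort(seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(g$matrix, p)
  fm <- read_peak_table(p)
  expect_equal(fm$intensities, g$matrix$intensities, tolerance = 1e-12)
  expect_identical(is.na(fm$intensities), is.na(g$matrix$intensities))
  expect_identical(fm$features$feature_id, g$matrix$features$feature_id)
  expect_identical(fm$features$is_standard, g$matrix$features$is_standard)
})

test_that("the parser enforces the dialect and maps NA cells to missing", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,rt,S1,S2",
               "F1,100.5,1.2,1000,NA",
               "F2,200.5,2.2,,3000",
               "F3,300.5,3.2,4000,5000"), p)
  fm <- read_peak_table(p)
  expect_equal(dim(fm$intensities), c(2, 3))
  expect_true(is.na(fm$intensities["S2", "F1"]))
  expect_true(is.na(fm$intensities["S1", "F2"]))
  expect_false(any(fm$intensities == 0, na.rm = TRUE))

  pdup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,rt,S1", "F1,100,1,10", "F1,200,2,20"), pdup)
  expect_error(read_peak_table(pdup), "duplicate feature_id")
  pbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,rt,S1", "F1,100,1,oops"), pbad)
  expect_error(read_peak_table(pbad), "row 1, column 'S1'")
  pmiss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,rt,S1", "F1,1,10"), pmiss)
  expect_error(read_peak_table(pmiss), "mz")
  expect_error(read_peak_table("no/such/file.csv"), "not found")
})

test_that("minimum-height filtering keeps the boundary and preserves samples", {
  x <- matrix(c(29999, 100, 30000, 200, 50000, 1), 2, 3)
  fm <- tiny_feature_matrix(x)
  out <- filter_min_height(fm, 30000)
  expect_identical(out$features$feature_id, c("F2", "F3")) # max 29999 removed
  expect_identical(rownames(out$intensities), rownames(fm$intensities))
  expect_identical(filter_min_height(fm, 0)$features$feature_id, fm$features$feature_id)
  empty <- filter_min_height(fm, 1e9)
  expect_equal(ncol(empty$intensities), 0)
  expect_equal(nrow(empty$intensities), 2)
})

make_is_matrix <- function(x_other, is_vals) {
  # two biological features + three standards
  x <- cbind(x_other, is_vals)
  rownames(x) <- paste0("S", seq_len(nrow(x)))
  feats <- data.frame(
    feature_id = c(paste0("F", seq_len(ncol(x_other))),
                   "IS_phe_d2", "IS_cholic_d4", "IS_lysoPC19_0"),
    mz = c(150 + seq_len(ncol(x_other)), 167.0915, 412.3127, 537.3794),
    rt = c(seq_len(ncol(x_other)), 3.2, 11.5, 16.8),
    is_standard = c(rep(FALSE, ncol(x_other)), rep(TRUE, 3)))
  colnames(x) <- feats$feature_id
  feature_matrix(x, feats)
}

test_that("internal-standard normalization has the contracted arithmetic", {
  is_set <- internal_standard_set(c("IS_phe_d2", "IS_cholic_d4", "IS_lysoPC19_0"))
  # sample 1: IS geometric mean 2000; sample 2: 500 -> reference sqrt(2000*500) = 1000
  fm <- make_is_matrix(matrix(c(1000, 800), 2, 1),
                       rbind(c(2000, 2000, 2000), c(500, 500, 500)))
  out <- normalize_internal_standards(fm, is_set)
  expect_equal(unname(out$intensities["S1", "F1"]), 500) # 1000 * 1000/2000
  expect_equal(unname(out$intensities["S2", "F1"]), 1600) # 800 * 1000/500
  expect_true(all(out$features$is_standard[out$features$feature_id %in% is_set$feature_id]))

  # scale invariance: against a fixed reference, multiplying one sample's
  # whole row (standards included) leaves its normalized values unchanged
  outr <- normalize_internal_standards(fm, is_set, reference = 1000)
  fm2 <- fm; fm2$intensities["S1", ] <- fm$intensities["S1", ] * 10
  out2 <- normalize_internal_standards(feature_matrix(fm2$intensities, fm2$features),
                                       is_set, reference = 1000)
  expect_equal(out2$intensities["S1", "F1"], outr$intensities["S1", "F1"], tolerance = 1e-12)
  expect_equal(out2$intensities["S2", "F1"], outr$intensities["S2", "F1"], tolerance = 1e-12)
  # with the data-derived reference the relative structure is still invariant
  out2d <- normalize_internal_standards(feature_matrix(fm2$intensities, fm2$features), is_set)
  expect_equal(out2d$intensities["S1", "F1"] / out2d$intensities["S2", "F1"],
               out$intensities["S1", "F1"] / out$intensities["S2", "F1"],
               tolerance = 1e-12)

  # equal IS everywhere -> identity
  fme <- make_is_matrix(matrix(c(1000, 800), 2, 1),
                        rbind(c(700, 900, 1100), c(700, 900, 1100)))
  oute <- normalize_internal_standards(fme, is_set)
  expect_equal(oute$intensities[, "F1"], fme$intensities[, "F1"], tolerance = 1e-12)

  # idempotence
  outo <- normalize_internal_standards(out, is_set)
  expect_lt(max(abs(outo$intensities / out$intensities - 1)), 1e-9)

  fmb <- fm; fmb$intensities["S2", "IS_phe_d2"] <- NA
  expect_error(normalize_internal_standards(fmb, is_set), "S2")
})

test_that("QC CV filtering uses sd/mean with a strict bound", {
  x <- matrix(1000, 3, 2)
  fm <- tiny_feature_matrix(x, n_features = 2)
  qc <- tiny_feature_matrix(rbind(c(100, 50), c(100, 150)))
  qc <- feature_matrix(qc$intensities[, 1:2], fm$features)
  out <- filter_qc_cv(fm, qc, cv_max = 0.15)
  # F1: CV 0 kept; F2: sd/mean = 70.71/100 = 0.707 removed
  expect_identical(out$features$feature_id, "F1")
  expect_identical(filter_qc_cv(fm, qc, cv_max = Inf)$features$feature_id,
                   c("F1", "F2"))
  qc0 <- feature_matrix(rbind(c(0, 100), c(0, 110)), fm$features)
  expect_warning(out0 <- filter_qc_cv(fm, qc0, cv_max = 0.5), "QC mean 0")
  expect_identical(out0$features$feature_id, "F2")
  expect_error(filter_qc_cv(fm, feature_matrix(qc$intensities[1, , drop = FALSE], fm$features)),
               ">= 2")
})

test_that("imputation follows the half-min and zero conventions", {
  x <- matrix(c(10, NA, 20, 5, 6, 7), 3, 2)
  fm <- tiny_feature_matrix(x, n_features = 2)
  out <- impute_missing(fm)
  expect_equal(unname(out$intensities[, "F1"]), c(10, 5, 20))
  expect_equal(unname(out$intensities[, "F2"]), c(5, 6, 7)) # untouched
  outz <- impute_missing(fm, "zero")
  expect_equal(unname(outz$intensities[2, "F1"]), 0)
  expect_identical(impute_missing(out)$intensities, out$intensities)
  xa <- matrix(c(NA, NA, 1, 2), 2, 2)
  expect_error(impute_missing(tiny_feature_matrix(xa, n_features = 2)), "filter")
})
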