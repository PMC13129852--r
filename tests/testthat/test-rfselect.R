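test_that("feature-space partitions are balanced, exhaustive and reproducible", {
  part <- partition_feature_space(146880, 10, seed = 4)
  sizes <- tabulate(part$assignment, 10)
  expect_true(all(sizes == 14688))
  expect_equal(sort(unique(part$assignment)), 1:10)
  expect_identical(part$assignment, partition_feature_space(146880, 10, seed = 4)$assignment)

  p11 <- partition_feature_space(11, 10, seed = 1)
  s11 <- sort(tabulate(p11$assignment, 10))
  expect_equal(s11, c(rep(1, 9), 2))
  expect_equal(tabulate(partition_feature_space(10, 10)$assignment, 10), rep(1, 10))
  expect_error(partition_feature_space(5, 10), "exceeds")
  expect_error(partition_feature_space(10, 0), ">= 1")
})

test_that("subset ranking surfaces a strong planted marker and nulls a constant one", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(2^rnorm(120 * 200, 15, 0.5), 120, 200)
    x[1:60, 7] <- x[1:60, 7] * 2^3 # one marker, log2FC = 3
    x[, 13] <- 1000 # constant feature
    colnames(x) <- sprintf("F%03d", 1:200)
    y <- rep(c("case", "control"), each = 60)
    r <- rank_subset_features(x, y, rf_config(seed = s))
    expect_true(all(is.finite(r$importance)), info = paste("seed", s))
    expect_true(all(r$importance >= 0))
    expect_equal(r$importance[r$feature_id == "F013"], 0)
    expect_equal(sort(r$rank), 1:200)
    if (r$rank[r$feature_id == "F007"] <= 2) hits <- hits + 1 # top 1% of 200
  }
  expect_gte(hits, 18)
  expect_error(rank_subset_features(matrix(1:10, 5), rep("a", 5)), "two classes")
})

test_that("permuted labels rarely promote any feature into the top 1%", {
  set.seed(99)
  x <- matrix(2^rnorm(100 * 200, 15, 0.5), 100, 200)
  colnames(x) <- sprintf("F%03d", 1:200)
  y <- rep(c("case", "control"), each = 50)
  top_counts <- integer(200)
  for (s in 1:20) {
    set.seed(1000 + s)
    r <- rank_subset_features(x, sample(y), rf_config(seed = s))
    top_counts[r$rank <= 2] <- top_counts[r$rank <= 2] + 1
  }
  expect_lte(max(top_counts), 5)
})

test_that("consensus aggregation flags per-subset top fractions and is monotone", {
  frag <- data.frame(
    feature_id = sprintf("F%03d", 1:40),
    subset = rep(1:2, each = 20),
    importance = c(20:1, 40:21),
    rank = rep(1:20, 2))
  sel <- select_consensus_features(frag, top_fraction = 0.1) # ceil(0.1*20)=2 per subset
  expect_equal(sel$n_selected, 4)
  expect_setequal(sel$consensus, c("F001", "F002", "F021", "F022"))
  expect_equal(sum(sel$ranking$selected), 4)
  # monotonicity: growing top_fraction never drops a selected feature
  prev <- character(0)
  for (tf in c(0.05, 0.1, 0.25, 0.5, 1)) {
    cur <- select_consensus_features(frag, tf)$consensus
    expect_true(all(prev %in% cur), info = paste("tf", tf))
    prev <- cur
  }
  expect_equal(length(select_consensus_features(frag, 1)$consensus), 40)
  one <- select_consensus_features(frag[frag$subset == 1, ], 0.05) # top-1
  expect_identical(one$consensus, "F001")
  expect_error(select_consensus_features(frag, 0), "top_fraction")
  expect_error(select_consensus_features(rbind(frag, frag[1, ]), 0.1), "exactly one subset")
})

test_that("consensus evaluation uses the ceiling held-out convention and separates signal", {
  g <- generate_untargeted_cohort(cohort_spec(
    n_cases = 172, n_controls = 115, n_features = 60,
    n_markers_down = 10, n_markers_up = 0, effect_log2fc_range = c(4, 5),
    missing_rate = 0, seed = 31))
  x <- g$matrix$intensities[, !g$matrix$features$is_standard]
  rep <- evaluate_feature_set(x[, g$truth$marker_ids], g$meta$group,
                              rf_config(seed = 3), case = "case")
  expect_equal(rep$n_cases + rep$n_controls, 87) # ceiling(0.3 * 287)
  expect_gte(rep$accuracy, 0.95)
  expect_error(evaluate_feature_set(x[, 0], g$meta$group), "empty")
})

test_that("held-out accuracy under permuted labels sits at chance", {
  set.seed(7)
  x <- matrix(2^rnorm(200 * 30, 15, 0.5), 200, 30)
  colnames(x) <- sprintf("F%02d", 1:30)
  y <- sample(rep(c("case", "control"), each = 100))
  accs <- vapply(1:5, function(s)
    evaluate_feature_set(x, y, rf_config(seed = s), case = "case")$accuracy,
    numeric(1))
  bounds <- qbinom(c(0.005, 0.995), 60 * 5, 0.5) / (60 * 5)
  expect_gte(mean(accs), bounds[1])
  expect_lte(mean(accs), bounds[2])
})

test_that("stability selection counts cross-run support", {
  g <- small_cohort(seed = 8)
  fm <- impute_missing(g$matrix)
  x <- fm$intensities[, !fm$features$is_standard]
  st <- subspace_select_stable(x, g$meta$group, k = 4, top_fraction = 0.1,
                               config = rf_config(seed = 5), n_runs = 4,
                               min_support = 3)
  expect_true(all(st$support[st$consensus] >= 3))
  expect_true(all(st$support <= 4))
  # markers at the default effect size dominate the stable set
  expect_gte(mean(g$truth$marker_ids %in% st$consensus), 0.7)
})
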