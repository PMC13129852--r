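test_that("Youden cutoff handles separable, degenerate and oracle-checked cases", {
  # controls high, cases low, fully separable below-positive
  v <- c(1, 2, 3, 10, 11, 12)
  y <- rep(c("case", "control"), each = 3)
  rec <- youden_cutoff(v, y, case = "case")
  expect_equal(rec$direction, "below")
  expect_equal(rec$cutoff, 6.5) # midpoint of the separating gap
  expect_equal(rec$j, 1)
  expect_false(rec$degenerate)

  const <- youden_cutoff(rep(5, 10), rep(c("case", "control"), 5))
  expect_true(const$degenerate)
  expect_equal(const$j, 0)

  set.seed(12)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    vv <- round(rnorm(n, 0, 2), 1)
    yy <- sample(rep(c("case", "control"), length.out = n))
    if (length(unique(yy)) < 2) next
    r <- youden_cutoff(vv, yy, case = "case")
    expect_equal(r$j, youden_oracle(vv, yy, "case", r$direction), tolerance = 1e-12)
    # J at the returned cutoff is reproducible from the data
    pos <- if (r$direction == "below") vv < r$cutoff else vv > r$cutoff
    expect_equal(mean(pos[yy == "case"]) + mean(!pos[yy != "case"]) - 1, r$j,
                 tolerance = 1e-12)
  }
})

test_that("subgroup comparison picks the right test and reports exclusions", {
  set.seed(4)
  v <- rnorm(100)
  s2 <- rep(c("a", "b"), 50)
  r2 <- subgroup_compare(v, s2)
  expect_equal(r2$test, "mann-whitney")
  expect_equal(sum(r2$groups$n), 100)
  s3 <- rep(c("a", "b", "c"), length.out = 100)
  expect_equal(subgroup_compare(v, s3)$test, "kruskal-wallis")

  shifted <- c(rnorm(50), rnorm(50, 5))
  expect_lt(subgroup_compare(shifted, rep(c("a", "b"), each = 50))$p, 0.001)

  s_small <- c(rep("a", 50), rep("b", 48), "tiny", "tiny")
  expect_warning(rs <- subgroup_compare(v, s_small), "excluded: tiny")
  expect_equal(rs$n_excluded, 2)
  expect_equal(rs$n_used + rs$n_excluded, 100)
  expect_error(subgroup_compare(v, rep("a", 100)), ">= 2 strata")
})

test_that("subgroup tests are invariant under monotone transforms", {
  set.seed(9)
  v <- rlnorm(80)
  s <- rep(c("a", "b"), 40)
  p1 <- subgroup_compare(v, s)$p
  expect_equal(subgroup_compare(log(v), s)$p, p1, tolerance = 1e-12)
  expect_equal(subgroup_compare(rank(v), s)$p, p1, tolerance = 1e-12)
  g <- factor(rep(c("I", "II", "III", "IV"), each = 20), ordered = TRUE)
  t1 <- stage_trend_test(v, g)
  expect_equal(stage_trend_test(exp(v), g)$p, t1$p, tolerance = 1e-12)
})

test_that("the stage trend test detects ordered decreases and respects direction", {
  set.seed(2)
  v <- c(rnorm(10, 10, 0.1), rnorm(10, 8, 0.1), rnorm(10, 6, 0.1), rnorm(10, 4, 0.1))
  g <- rep(c("I", "II", "III", "IV"), each = 10)
  tt <- stage_trend_test(v, g, "decreasing")
  expect_lt(tt$p, 0.01)
  # reversing the stage order flips the one-sided tail
  rev_g <- factor(g, levels = c("IV", "III", "II", "I"), ordered = TRUE)
  tr <- stage_trend_test(v, rev_g, "decreasing", stage_levels = c("IV", "III", "II", "I"))
  expect_equal(tr$p, 1 - tt$p, tolerance = 1e-9) # continuous values: no ties
  expect_error(stage_trend_test(v, rep(c("I", "II", "X", "IV"), each = 10)), "unknown stage")
  expect_error(stage_trend_test(v[1:20], g[1:20]), ">= 3 ordered groups")
})

test_that("trend-test null p-values are well calibrated and permutation agrees", {
  set.seed(30)
  ok <- 0
  for (s in 1:10) {
    v <- rnorm(60)
    g <- rep(c("I", "II", "III", "IV"), 15)
    if (stage_trend_test(v, g)$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
  set.seed(31)
  v <- rnorm(36); g <- rep(c("I", "II", "III"), each = 12)
  pn <- stage_trend_test(v, g)$p
  pp <- stage_trend_test(v, g, method = "permutation", n_perm = 4000, seed = 7)$p
  expect_lt(abs(pn - pp), 0.05)
})

test_that("age correlation covers the exact and null regimes", {
  ages <- 30:79
  expect_equal(age_correlation(ages + 0.5, ages)$rho, 1)
  expect_equal(age_correlation(-ages, ages)$rho, -1)
  set.seed(3)
  ok <- 0
  for (s in 1:10) {
    r <- age_correlation(rnorm(115), rnorm(115, 40, 12))
    if (r$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
  expect_warning(rc <- age_correlation(rep(1, 10), 1:10), "constant")
  expect_true(is.na(rc$rho))
  expect_error(age_correlation(1:4, 1:4), "n >= 5")
})

test_that("stage and age dichotomies follow the conventions", {
  expect_equal(as.character(stage_early_late(c("I", "II", "III", "IV", NA))),
               c("early", "early", "late", "late", NA))
  sp <- age_median_split(c(30, 40, 50, 60, 70))
  expect_equal(sp$median, 50)
  expect_equal(as.character(sp$group), c("<median", "<median", ">=median", ">=median", ">=median"))
})
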