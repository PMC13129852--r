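test_that("the logistic fit recovers a known single-predictor closed form", {
  # single binary predictor: coefficient = log odds ratio of the 2x2 table
  x <- rep(c(1, 1, 0, 0), c(30, 10, 15, 25)) # exposed cases/ctrl, unexposed cases/ctrl
  y <- rep(c("case", "control", "case", "control"), c(30, 10, 15, 25))
  m <- fit_logistic_panel(data.frame(marker = x), y, case = "case")
  lor <- log((30 * 25) / (10 * 15))
  expect_equal(unname(m$coefficients["marker"]), lor, tolerance = 1e-8)
  expect_true(m$converged)
  expect_false(m$separation)
})

test_that("constant concentrations reduce the panel to the prevalence intercept", {
  conc <- data.frame(a = rep(3, 60))
  y <- rep(c("case", "control"), c(20, 40))
  m <- suppressWarnings(fit_logistic_panel(conc, y, case = "case"))
  pr <- predict_probability(m, conc)
  expect_equal(unname(pr), rep(20 / 60, 60), tolerance = 1e-6)
})

test_that("probability predictions respect the logistic link and sample order", {
  m <- structure(list(metabolites = c("a", "b"), intercept = 0,
                      coefficients = c(a = 1, b = -1)), class = "panel_model")
  conc <- data.frame(a = c(0, 10, 1), b = c(0, 0, 1))
  pr <- predict_probability(m, conc)
  expect_equal(pr[1], 0.5)           # linear score 0
  expect_gt(pr[2], 0.9999)           # hugely positive score
  expect_equal(pr[3], 0.5)
  perm <- c(3, 1, 2)
  expect_equal(predict_probability(m, conc[perm, ]), pr[perm])
  expect_error(predict_probability(m, conc["a"]), "missing metabolite")
})

test_that("separation is detected and the ridge fallback produces finite coefficients", {
  set.seed(14)
  conc <- data.frame(m = c(rnorm(20, 10, 0.1), rnorm(20, 0, 0.1)))
  y <- rep(c("case", "control"), each = 20)
  mflag <- fit_logistic_panel(conc, y, case = "case")
  expect_true(mflag$separation)
  mpen <- fit_logistic_panel(conc, y, case = "case", penalized = TRUE)
  expect_true(all(is.finite(c(mpen$intercept, mpen$coefficients))))
  expect_true(mpen$provenance$penalized)
})

test_that("validation-split mode holds out a ceiling-sized stratified test set", {
  set.seed(2)
  conc <- data.frame(m = rnorm(94))
  y <- rep(c("case", "control"), each = 47)
  m <- fit_logistic_panel(conc, y, mode = "validation-split", case = "case")
  expect_equal(length(m$provenance$test_indices), 29) # ceiling(0.3 * 94)
  expect_equal(m$provenance$n_fit, 65)
  te <- m$provenance$test_indices
  expect_true(abs(sum(y[te] == "case") - sum(y[te] == "control")) <= 1)
})

test_that("metric-report identities hold for arbitrary confusion counts", {
  set.seed(10)
  for (i in 1:50) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tn <- sample(0:50, 1); fp <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    r <- metric_report(tp, fn, tn, fp)
    expect_equal(unname(r$counts["TP"] + r$counts["FN"]), r$n_cases)
    expect_equal(r$sensitivity, tp / (tp + fn))
    expect_equal(r$specificity, tn / (tn + fp))
    expect_equal(r$accuracy, (tp + tn) / (tp + fn + tn + fp))
    # accuracy decomposes exactly over the group-weighted rates
    expect_equal(r$accuracy,
                 (r$sensitivity * r$n_cases + r$specificity * r$n_controls) /
                   (r$n_cases + r$n_controls))
    expect_true(all(unlist(r$ci) >= 0 - 1e-9 & unlist(r$ci) <= 100 + 1e-9))
  }
})

test_that("published-rate reconstructions reproduce printed accuracies", {
  # sensitivity 85.1 / specificity 93.6 at 47/47 -> counts 40,7,44,3 -> 89.4%
  cts <- counts_from_rates(85.1, 93.6, 47, 47)
  expect_equal(unname(cts), c(40, 7, 44, 3))
  r <- metric_report(cts["TP"], cts["FN"], cts["TN"], cts["FP"])
  expect_equal(r$accuracy_pct, 89.4)
  expect_equal(r$sensitivity_pct, 85.1)
  expect_equal(r$specificity_pct, 93.6)
  cts2 <- counts_from_rates(80.9, 95.7, 47, 47)
  r2 <- metric_report(cts2["TP"], cts2["FN"], cts2["TN"], cts2["FP"])
  expect_equal(r2$accuracy_pct, 88.3) # 83/94
  expect_equal(r2$accuracy, 83 / 94)
})

test_that("proportion intervals match their closed forms", {
  w <- proportion_ci(46, 47, "wilson")
  z <- qnorm(0.975); ph <- 46 / 47; n <- 47
  lower <- (ph + z^2 / (2 * n) - z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  expect_equal(unname(w["lower"]), lower, tolerance = 1e-12)
  expect_equal(round_half_up(100 * w["lower"], 1), c(lower = 88.9))
  cp <- proportion_ci(46, 47, "clopper-pearson")
  expect_equal(unname(cp["upper"]), 0.975^(1 / 47), tolerance = 1e-10)
  expect_equal(unname(proportion_ci(0, 10, "clopper-pearson")["lower"]), 0)
  expect_error(proportion_ci(1, 0), "n must be")
})

test_that("DeLong AUC equals the rank AUC and behaves under label flips", {
  set.seed(5)
  v <- c(rnorm(25, 1), rnorm(25))
  y <- rep(c("case", "control"), each = 25)
  a <- auc_ci(v, y, case = "case")
  expect_identical(a$auc, auc_pair_oracle(v, y, "case"))
  b <- auc_ci(v, y, case = "control")
  expect_equal(b$auc, 1 - a$auc, tolerance = 1e-12)
  expect_equal(unname(b$ci), unname(1 - rev(a$ci)), tolerance = 1e-12)
  # perfect separation: degenerate CI clamped into [0, 1]
  p <- auc_ci(c(2, 3, 0, 1), c("case", "case", "control", "control"), case = "case")
  expect_equal(p$auc, 1)
  expect_lte(p$ci[2], 1)
  boot <- auc_ci(v, y, method = "bootstrap", n_boot = 200, case = "case", seed = 3)
  expect_equal(boot$auc, a$auc)
  expect_true(boot$ci[1] <= boot$auc && boot$auc <= boot$ci[2])
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  v <- c(rnorm(30, 0.8), rnorm(35))
  y <- rep(c("case", "control"), c(30, 35))
  a <- auc_ci(v, y, case = "case")
  ref <- pROC::ci.auc(pROC::roc(response = y, predictor = v, levels = c("control", "case"),
                                direction = "<", quiet = TRUE), method = "delong")
  expect_equal(a$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(unname(a$ci), as.numeric(ref[c(1, 3)]), tolerance = 1e-8)
})

test_that("covariate adjustment separates age-mediated from direct effects", {
  one_sim <- function(seed) {
    set.seed(seed)
    n <- 200
    y <- rep(c(1, 0), each = n / 2)
    age <- ifelse(y == 1, rnorm(n, 70, 9), rnorm(n, 42, 11))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    mediated <- 0.1 * age + rnorm(n, 0, 0.5)     # tracks age only
    direct <- -1.2 * y + 0.05 * age + rnorm(n)   # true group effect + confound
    lab <- ifelse(y == 1, "case", "control")
    adj <- adjust_covariates(data.frame(mediated = mediated, direct = direct),
                             lab, data.frame(age = age, sex = sex), case = "case")
    c(med_crude = adj$crude_p[1], med_adj = adj$adj_p[1],
      dir_adj = adj$adj_p[2])
  }
  res <- t(vapply(1:10, one_sim, numeric(3)))
  expect_gte(mean(res[, "med_crude"] < 0.05), 0.8)
  expect_gte(mean(res[, "med_adj"] > 0.05), 0.8)
  expect_gte(mean(res[, "dir_adj"] < 0.05), 0.8)
})

test_that("empty covariates give the crude model; singular designs are named", {
  set.seed(1)
  conc <- data.frame(m = rnorm(50))
  y <- rep(c("case", "control"), 25)
  a0 <- adjust_covariates(conc, y, NULL)
  expect_equal(a0$crude_beta, a0$adj_beta)
  expect_equal(a0$crude_p, a0$adj_p)
  expect_error(adjust_covariates(conc, y, data.frame(k = rep(2, 50))), "constant covariate")
  dup <- data.frame(age = rnorm(50))
  dup$age2 <- dup$age * 2
  expect_error(adjust_covariates(conc, y, dup), "collinear")
})
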