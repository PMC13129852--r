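# Stage-two interpretable diagnostics: the logistic-regression metabolite
# panel, confusion-matrix metrics with binomial confidence intervals, DeLong
# AUC intervals, and age/sex covariate adjustment.

#' Fit the logistic-regression metabolite panel
#'
#' Maximum-likelihood logistic regression (IRLS, convergence tolerance 1e-10,
#' at most 100 iterations) of case status on metabolite concentrations in
#' their native units. `mode = "discovery-train"` (default) fits on all
#' provided samples — the coefficients are then meant to be applied to an
#' independent cohort without retraining. `mode = "validation-split"` fits on
#' a stratified 70% split and records the held-out 30% (test size
#' `ceiling(0.3 n)`, e.g. 29 of 94) for evaluation.
#'
#' Perfect separation is detected (diverging coefficients or degenerate
#' fitted probabilities) and flagged; with `penalized = TRUE` a ridge-
#' penalized IRLS fit (small fixed penalty, intercept unpenalized) is
#' returned instead so the panel remains usable on separable data.
#'
#' @param concentrations data.frame or matrix, samples x metabolites; an
#'   optional `sample_id` column is carried along, all other columns must be
#'   numeric and complete.
#' @param labels two-class labels; first level (or `case`) is modeled as 1.
#' @param mode `"discovery-train"` or `"validation-split"`.
#' @param train_fraction training share in split mode.
#' @param penalized use a ridge fallback when separation is detected.
#' @param units optional named character vector of per-metabolite units,
#'   recorded in the model.
#' @param case optional case-level name.
#' @param seed seed for the stratified split.
#' @return list of class `panel_model`: `metabolites`, `intercept`,
#'   `coefficients`, `se`, `z`, `p`, `converged`, `separation`, `provenance`
#'   (mode, n, seed, test indices in split mode), `units`.
#' @export
fit_logistic_panel <- function(concentrations, labels,
                               mode = c("discovery-train", "validation-split"),
                               train_fraction = 0.70, penalized = FALSE,
                               units = NULL, case = NULL, seed = 1) {
  mode <- match.arg(mode)
  conc <- as.data.frame(concentrations)
  if ("sample_id" %in% names(conc)) conc$sample_id <- NULL
  if (!all(vapply(conc, is.numeric, logical(1)))) {
    stop("all concentration columns must be numeric", call. = FALSE)
  }
  if (anyNA(conc)) stop("missing concentrations are not allowed", call. = FALSE)
  y <- as_case_control(labels, case)
  if (nrow(conc) != length(y)) stop("concentrations and labels differ in length", call. = FALSE)

  test_idx <- integer(0)
  fit_rows <- seq_len(nrow(conc))
  if (mode == "validation-split") {
    test_idx <- stratified_test_indices(y, 1 - train_fraction,
                                        seed = derive_seed(seed, "panelsplit"))
    fit_rows <- setdiff(fit_rows, test_idx)
  }
  yb <- as.integer(y == levels(y)[1])
  d <- data.frame(..y.. = yb[fit_rows], conc[fit_rows, , drop = FALSE], check.names = FALSE)
  fit <- suppressWarnings(stats::glm(
    ..y.. ~ ., data = d, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0 # terms dropped as constant/collinear contribute nothing
  mu <- stats::fitted(fit)
  separation <- !fit$converged ||
    any(abs(cf[-1]) * apply(conc[fit_rows, , drop = FALSE], 2, stats::sd) > 30, na.rm = TRUE) ||
    (all(mu[d$..y.. == 1] > 1 - 1e-6) && all(mu[d$..y.. == 0] < 1e-6))
  se <- rep(NA_real_, length(cf))
  ok <- !is.na(stats::coef(fit))
  se[ok] <- sqrt(diag(stats::vcov(fit)))
  if (separation && penalized) {
    xm <- as.matrix(conc[fit_rows, , drop = FALSE])
    cf <- ridge_logistic(xm, d$..y.., lambda = 1e-3)
    se <- rep(NA_real_, length(cf))
  }
  structure(list(
    metabolites = names(conc),
    intercept = unname(cf[1]),
    coefficients = stats::setNames(unname(cf[-1]), names(conc)),
    se = stats::setNames(unname(se[-1]), names(conc)),
    z = stats::setNames(unname(cf[-1] / se[-1]), names(conc)),
    p = stats::setNames(unname(2 * stats::pnorm(-abs(cf[-1] / se[-1]))), names(conc)),
    converged = fit$converged, separation = separation,
    provenance = list(mode = mode, n_fit = length(fit_rows),
                      n_case = sum(yb[fit_rows]), seed = seed,
                      test_indices = test_idx, penalized = separation && penalized),
    units = units,
    classes = levels(y)
  ), class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("panel_model (", x$provenance$mode, ", n = ", x$provenance$n_fit, "): ",
      length(x$metabolites), " metabolites",
      if (x$separation) " [separation flagged]", "\n", sep = "")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 6))
  invisible(x)
}

#' Predicted case probability from a fitted panel
#'
#' @param model a [fit_logistic_panel()] result.
#' @param concentrations data.frame/matrix carrying the model's metabolite
#'   columns (any order; extra columns ignored).
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
predict_probability <- function(model, concentrations) {
  conc <- as.data.frame(concentrations)
  miss <- setdiff(model$metabolites, names(conc))
  if (length(miss)) stop("missing metabolite column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  xm <- as.matrix(conc[, model$metabolites, drop = FALSE])
  eta <- model$intercept + drop(xm %*% model$coefficients)
  unname(stats::plogis(eta))
}

#' Confusion-matrix classification metrics
#'
#' Builds the confusion matrix of predictions against labels and derives
#' sensitivity, specificity, accuracy, balanced accuracy and F1 (as
#' percentages, reported to one decimal with half rounded away from zero),
#' each with a 95% binomial confidence interval, plus the rank AUC when
#' continuous scores are supplied.
#'
#' @param predictions predicted classes, or numeric case probabilities /
#'   scores (thresholded at `threshold`).
#' @param labels true two-class labels; first level (or `case`) is positive.
#' @param threshold probability cutoff for numeric predictions (default 0.5).
#' @param case optional positive-class name.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"` for the
#'   proportion intervals.
#' @return A `metric_report` (see [metric_report()]); when scores are given
#'   it also carries `auc` with its DeLong interval.
#' @export
classification_metrics <- function(predictions, labels, threshold = 0.5,
                                   case = NULL, ci_method = "wilson") {
  y <- as_case_control(labels, case)
  if (!length(predictions)) stop("empty predictions", call. = FALSE)
  if (length(predictions) != length(y)) stop("predictions and labels differ in length", call. = FALSE)
  pos <- levels(y)[1]
  auc <- NULL
  if (is.numeric(predictions)) {
    auc <- auc_ci(predictions, y, case = pos)
    pred_class <- ifelse(predictions >= threshold, pos, levels(y)[2])
  } else {
    pred_class <- as.character(predictions)
  }
  tp <- sum(pred_class == pos & y == pos)
  fn <- sum(pred_class != pos & y == pos)
  tn <- sum(pred_class != pos & y != pos)
  fp <- sum(pred_class == pos & y != pos)
  rep <- metric_report(tp, fn, tn, fp, ci_method = ci_method)
  rep$auc <- auc
  rep
}

#' Build a metric report from confusion counts
#'
#' The arithmetic is exact on the integer counts: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/total, balanced accuracy =
#' mean of the rounded sensitivity and specificity percentages (the
#' convention used when rates are reported to one decimal), F1 =
#' 2TP/(2TP+FP+FN).
#'
#' @param tp,fn,tn,fp nonnegative integer confusion counts.
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @return list of class `metric_report` with `counts`, `n_cases`,
#'   `n_controls`, raw proportions (`sensitivity`, `specificity`,
#'   `accuracy`, `balanced_accuracy`, `f1`), the same as percentages rounded
#'   to one decimal (`*_pct`), and 95% CIs (`ci`, as percentages).
#' @export
metric_report <- function(tp, fn, tn, fp, ci_method = "wilson") {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  n_cases <- tp + fn; n_controls <- tn + fp; n <- n_cases + n_controls
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  sens <- if (n_cases > 0) tp / n_cases else NA_real_
  spec <- if (n_controls > 0) tn / n_controls else NA_real_
  acc <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  sens_pct <- round_half_up(100 * sens, 1)
  spec_pct <- round_half_up(100 * spec, 1)
  bal_pct <- round_half_up((sens_pct + spec_pct) / 2, 1)
  ci <- list(
    sensitivity = 100 * proportion_ci(tp, n_cases, ci_method),
    specificity = 100 * proportion_ci(tn, n_controls, ci_method),
    accuracy = 100 * proportion_ci(tp + tn, n, ci_method)
  )
  structure(list(
    counts = c(TP = tp, FN = fn, TN = tn, FP = fp),
    n_cases = n_cases, n_controls = n_controls,
    sensitivity = sens, specificity = spec, accuracy = acc,
    balanced_accuracy = (sens + spec) / 2, f1 = f1,
    sensitivity_pct = sens_pct, specificity_pct = spec_pct,
    accuracy_pct = round_half_up(100 * acc, 1),
    balanced_accuracy_pct = bal_pct,
    f1_pct = round_half_up(100 * f1, 1),
    ci = ci, ci_method = ci_method
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (n = ", x$n_cases, " cases / ", x$n_controls, " controls)\n",
      "  TP ", x$counts["TP"], "  FN ", x$counts["FN"],
      "  TN ", x$counts["TN"], "  FP ", x$counts["FP"], "\n",
      "  sensitivity ", x$sensitivity_pct, "%  specificity ", x$specificity_pct,
      "%  accuracy ", x$accuracy_pct, "%  F1 ", x$f1_pct, "%\n", sep = "")
  if (!is.null(x$auc)) {
    cat("  AUC ", round(x$auc$auc, 4), " (95% CI ", round(x$auc$ci[1], 4), "-",
        round(x$auc$ci[2], 4), ", ", x$auc$method, ")\n", sep = "")
  }
  invisible(x)
}

#' Reconstruct confusion counts from printed rates
#'
#' Inverse bookkeeping for published tables: counts are the rates applied to
#' the group sizes, rounded to the nearest integer.
#'
#' @param sensitivity,specificity rates as percentages.
#' @param n_cases,n_controls group sizes.
#' @return Named integer vector `TP, FN, TN, FP`.
#' @export
counts_from_rates <- function(sensitivity, specificity, n_cases, n_controls) {
  tp <- round(sensitivity / 100 * n_cases)
  tn <- round(specificity / 100 * n_controls)
  c(TP = tp, FN = n_cases - tp, TN = tn, FP = n_controls - tn)
}

#' Binomial proportion confidence interval
#'
#' Wilson score interval (default) or exact Clopper-Pearson.
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` on the proportion scale.
#' @export
proportion_ci <- function(successes, n, method = c("wilson", "clopper-pearson"),
                          conf = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(successes >= 0, successes <= n)
  a <- 1 - conf
  if (method == "wilson") {
    z <- stats::qnorm(1 - a / 2)
    ph <- successes / n
    den <- 1 + z^2 / n
    ctr <- ph + z^2 / (2 * n)
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))
    c(lower = (ctr - hw) / den, upper = (ctr + hw) / den)
  } else {
    lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
    hi <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
    c(lower = lo, upper = hi)
  }
}

#' AUC with a 95% confidence interval
#'
#' The point estimate is the rank (pair-counting) AUC; the interval is the
#' asymptotic placement-value (DeLong) interval by default, or a seeded
#' stratified bootstrap. Degenerate intervals are clamped to \[0, 1\].
#'
#' @param scores numeric vector (higher = more case-like under the default
#'   orientation).
#' @param labels two-class labels; first level (or `case`) is positive.
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @param case optional positive-class name.
#' @param seed bootstrap seed.
#' @return list of class `auc_ci`: `auc`, `ci = c(lower, upper)`, `se`
#'   (DeLong only), `method`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   n_boot = 2000, conf = 0.95, case = NULL, seed = 1) {
  method <- match.arg(method)
  y <- as_case_control(labels, case)
  ic <- y == levels(y)[1]
  m <- sum(ic); n <- sum(!ic)
  if (m == 0 || n == 0) stop("both classes required", call. = FALSE)
  auc_point <- function(sc, ici) {
    r <- rank(sc)
    (sum(r[ici]) - sum(ici) * (sum(ici) + 1) / 2) / (sum(ici) * sum(!ici))
  }
  auc <- auc_point(scores, ic)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "delong") {
    cs <- scores[ic]; ct <- scores[!ic]
    # placement values: V10_i = fraction of controls each case outranks
    v10 <- vapply(cs, function(s) (sum(s > ct) + 0.5 * sum(s == ct)) / n, numeric(1))
    v01 <- vapply(ct, function(s) (sum(cs > s) + 0.5 * sum(cs == s)) / m, numeric(1))
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
    ci <- c(auc - z * se, auc + z * se)
    out <- list(auc = auc, ci = pmin(pmax(ci, 0), 1), se = se, method = "delong")
  } else {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(n_boot), function(b) {
      i1 <- sample(which(ic), m, replace = TRUE)
      i0 <- sample(which(!ic), n, replace = TRUE)
      sc <- c(scores[i1], scores[i0])
      auc_point(sc, rep(c(TRUE, FALSE), c(m, n)))
    }, numeric(1))
    ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    out <- list(auc = auc, ci = ci, se = stats::sd(bs), method = "bootstrap")
  }
  class(out) <- "auc_ci"
  out
}

#' Covariate-adjusted per-metabolite association
#'
#' For each metabolite, fits the crude logistic model `status ~ metabolite`
#' and the adjusted model `status ~ metabolite + covariates` (age and sex in
#' the standard analysis) and reports crude and adjusted coefficient,
#' standard error and Wald p side by side. With an empty covariate table the
#' adjusted model equals the crude model.
#'
#' @param concentrations samples x metabolites data.frame (numeric,
#'   complete; `sample_id` ignored).
#' @param labels two-class labels.
#' @param covariates data.frame of covariate columns (e.g. `age`, `sex`),
#'   complete, or `NULL`/zero columns for no adjustment.
#' @param case optional case-level name.
#' @return data.frame, one row per metabolite: `metabolite, crude_beta,
#'   crude_se, crude_p, adj_beta, adj_se, adj_p`.
#' @export
adjust_covariates <- function(concentrations, labels, covariates = NULL, case = NULL) {
  conc <- as.data.frame(concentrations)
  if ("sample_id" %in% names(conc)) conc$sample_id <- NULL
  y <- as_case_control(labels, case)
  yb <- as.integer(y == levels(y)[1])
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0
  if (has_cov) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("covariates must be complete", call. = FALSE)
    if (nrow(covariates) != length(y)) stop("covariates and labels differ in length", call. = FALSE)
    const <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
    if (any(const)) stop("singular design: constant covariate column '",
                         names(covariates)[const][1], "'", call. = FALSE)
  }
  out <- lapply(names(conc), function(mb) {
    d0 <- data.frame(..y.. = yb, m = conc[[mb]])
    f0 <- suppressWarnings(stats::glm(..y.. ~ m, data = d0, family = stats::binomial(),
                                      control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    s0 <- summary(f0)$coefficients["m", ]
    if (has_cov) {
      d1 <- cbind(d0, covariates)
      f1 <- suppressWarnings(stats::glm(..y.. ~ ., data = d1, family = stats::binomial(),
                                        control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
      if (any(is.na(stats::coef(f1)))) {
        bad <- names(stats::coef(f1))[is.na(stats::coef(f1))][1]
        stop("singular design: column '", bad, "' is collinear", call. = FALSE)
      }
      s1 <- summary(f1)$coefficients["m", ]
    } else {
      s1 <- s0
    }
    data.frame(metabolite = mb,
               crude_beta = s0[1], crude_se = s0[2], crude_p = s0[4],
               adj_beta = s1[1], adj_se = s1[2], adj_p = s1[4],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

# Ridge-penalized logistic regression by IRLS on standardized predictors;
# the intercept is unpenalized. Returns coefficients on the original scale,
# intercept first. Used as the fallback when separation is detected.
ridge_logistic <- function(x, y, lambda = 1e-3, maxit = 200, tol = 1e-10) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- cbind(1, sweep(sweep(x, 2, ctr), 2, scl, "/"))
  p <- ncol(xs)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(xs, xs * w) + pen, crossprod(xs, w * z))
    if (max(abs(new - beta)) < tol * (1 + max(abs(beta)))) { beta <- drop(new); break }
    beta <- drop(new)
  }
  b <- beta[-1] / scl
  c("(Intercept)" = beta[1] - sum(b * ctr), stats::setNames(b, colnames(x)))
}
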