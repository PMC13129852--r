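# Cutoff determination and subgroup robustness analyses. All tests are
# rank-based, hence invariant under strictly increasing transforms of the
# measured concentrations.

#' Youden-optimal diagnostic cutoff
#'
#' Scans candidate thresholds (midpoints between adjacent sorted unique
#' values) and returns the cutoff maximizing Youden's J = sensitivity +
#' specificity - 1. Ties are broken toward higher specificity, then the
#' smaller cutoff. The test-positive direction is auto-detected from the AUC
#' orientation: markers reduced in disease are called positive below the
#' cutoff.
#'
#' @param values numeric marker values.
#' @param labels two-class labels; first level (or `case`) is the disease
#'   class.
#' @param direction `"auto"` (default), `"below"` (value < cutoff =
#'   test-positive) or `"above"`.
#' @param case optional case-level name.
#' @return list of class `cutoff_record`: `cutoff`, `direction`,
#'   `sensitivity`, `specificity`, `j`, `degenerate` (TRUE when no threshold
#'   separates at all, e.g. constant values).
#' @export
youden_cutoff <- function(values, labels, direction = c("auto", "below", "above"),
                          case = NULL) {
  direction <- match.arg(direction)
  y <- as_case_control(labels, case)
  keep <- !is.na(values)
  values <- values[keep]; y <- droplevels(y[keep])
  if (nlevels(y) < 2) stop("both classes required", call. = FALSE)
  if (direction == "auto") {
    direction <- if (feature_auc(values, y)$auc >= 0.5) "above" else "below"
  }
  u <- sort(unique(values))
  degenerate <- length(u) < 2
  cand <- if (degenerate) u else (u[-1] + u[-length(u)]) / 2
  ic <- y == levels(y)[1]
  best <- NULL
  for (cut in cand) {
    pos <- if (direction == "below") values < cut else values > cut
    sens <- mean(pos[ic]); spec <- mean(!pos[!ic])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && cut < best$cutoff)))) {
      best <- list(cutoff = cut, direction = direction, sensitivity = sens,
                   specificity = spec, j = j)
    }
  }
  best$degenerate <- degenerate || best$j <= 0
  class(best) <- "cutoff_record"
  best
}

#' @export
print.cutoff_record <- function(x, ...) {
  cat("cutoff ", signif(x$cutoff, 6), " (test-positive ", x$direction,
      "): sensitivity ", round_half_up(100 * x$sensitivity, 1),
      "%, specificity ", round_half_up(100 * x$specificity, 1),
      "%, J = ", round(x$j, 4), if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Compare a marker across subgroups
#'
#' Two strata: two-sided Mann-Whitney; more: Kruskal-Wallis. Strata with
#' fewer than `min_n` observations are excluded with a warning; exclusions
#' are reported, never silent.
#'
#' @param values numeric marker values.
#' @param strata stratum labels aligned with `values` (`NA` excluded).
#' @param min_n minimum stratum size (default 3).
#' @return list of class `strata_result`: `test`, `statistic`, `p`, `groups`
#'   (data.frame stratum/n/median), `n_used`, `n_excluded`.
#' @export
subgroup_compare <- function(values, strata, min_n = 3) {
  keep <- !is.na(values) & !is.na(strata)
  v <- values[keep]; s <- factor(strata[keep])
  tab <- table(s)
  small <- names(tab)[tab < min_n]
  if (length(small)) {
    warning("stratum(s) below n = ", min_n, " excluded: ", paste(small, collapse = ", "))
    sel <- !(s %in% small)
    v <- v[sel]; s <- droplevels(s[sel])
  }
  if (nlevels(s) < 2) stop("need >= 2 strata with n >= ", min_n, call. = FALSE)
  if (nlevels(s) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(v ~ s, exact = FALSE))
    test <- "mann-whitney"
  } else {
    ht <- stats::kruskal.test(v ~ s)
    test <- "kruskal-wallis"
  }
  groups <- data.frame(stratum = levels(s),
                       n = as.integer(table(s)),
                       median = as.numeric(tapply(v, s, stats::median)),
                       stringsAsFactors = FALSE)
  structure(list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
                 groups = groups, n_used = length(v),
                 n_excluded = sum(keep) - length(v)),
            class = "strata_result")
}

#' @export
print.strata_result <- function(x, ...) {
  cat("subgroup comparison (", x$test, "): p = ", signif(x$p, 4), "\n", sep = "")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Jonckheere-Terpstra test for an ordered stage trend
#'
#' Tests a monotone trend of a marker across ordered groups (clinical stages
#' I < II < III < IV) against the null of identical distributions. The
#' statistic is the sum of pairwise Mann-Whitney counts over ordered group
#' pairs (ties counted one half); p-values use the tie-corrected normal
#' approximation, or a seeded permutation distribution for small samples.
#'
#' @param values numeric marker values.
#' @param stages ordered factor, or a vector coercible with `stage_levels`.
#' @param alternative `"decreasing"` (default: values fall with advancing
#'   stage), `"increasing"`, or `"two.sided"`.
#' @param method `"normal"` (default) or `"permutation"`.
#' @param stage_levels level order when `stages` is not an ordered factor.
#' @param n_perm permutation count.
#' @param seed permutation seed.
#' @return list of class `trend_test`: `statistic` (J), `mean`, `sd`, `z`,
#'   `p`, `alternative`, `method`, `group_n`.
#' @export
stage_trend_test <- function(values, stages,
                             alternative = c("decreasing", "increasing", "two.sided"),
                             method = c("normal", "permutation"),
                             stage_levels = c("I", "II", "III", "IV"),
                             n_perm = 2000, seed = 1) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(stages)
  v <- values[keep]
  if (is.ordered(stages)) {
    g <- droplevels(stages[keep])
  } else {
    s <- as.character(stages[keep])
    bad <- setdiff(unique(s), stage_levels)
    if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    g <- droplevels(factor(s, levels = stage_levels, ordered = TRUE))
  }
  tab <- table(g)
  if (length(tab) < 3 || any(tab < 3)) stop("need >= 3 ordered groups with n >= 3", call. = FALSE)

  jt_stat <- function(v, g) {
    lv <- levels(g)
    jj <- 0
    for (i in seq_len(length(lv) - 1)) {
      for (k in (i + 1):length(lv)) {
        a <- v[g == lv[i]]; b <- v[g == lv[k]]
        jj <- jj + sum(outer(b, a, ">")) + 0.5 * sum(outer(b, a, "=="))
      }
    }
    jj
  }
  J <- jt_stat(v, g)
  n <- length(v); ni <- as.numeric(tab)
  mu <- (n^2 - sum(ni^2)) / 4
  if (method == "normal") {
    tj <- as.numeric(table(v)) # tie group sizes
    s1 <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    s2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
    s3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
    vr <- s1 / 72 + s2 / (36 * n * (n - 1) * (n - 2)) + s3 / (8 * n * (n - 1))
    z <- (J - mu) / sqrt(vr)
    p <- switch(alternative,
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    out <- list(statistic = J, mean = mu, sd = sqrt(vr), z = z, p = p)
  } else {
    set.seed(as.integer(seed))
    null <- vapply(seq_len(n_perm), function(b) jt_stat(sample(v), g), numeric(1))
    p <- switch(alternative,
                increasing = (1 + sum(null >= J)) / (1 + n_perm),
                decreasing = (1 + sum(null <= J)) / (1 + n_perm),
                two.sided = (1 + sum(abs(null - mu) >= abs(J - mu))) / (1 + n_perm))
    out <- list(statistic = J, mean = mu, sd = stats::sd(null), z = (J - mu) / stats::sd(null), p = p)
  }
  structure(c(out, list(alternative = alternative, method = method,
                        group_n = tab)),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat("Jonckheere-Terpstra trend (", x$alternative, ", ", x$method, "): J = ",
      x$statistic, ", z = ", round(x$z, 3), ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Correlation between a marker and age
#'
#' Spearman rank correlation with two-sided p (the standard check that a
#' candidate marker is not merely tracking chronological age, typically run
#' within the healthy controls).
#'
#' @param values numeric marker values.
#' @param ages numeric ages aligned with `values`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `rho`, `p`, `n`, `method`; `rho` is `NA` with a warning for
#'   constant values.
#' @export
age_correlation <- function(values, ages, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(ages)
  v <- values[keep]; a <- ages[keep]
  if (length(v) < 5) stop("need n >= 5", call. = FALSE)
  if (length(unique(v)) < 2 || length(unique(a)) < 2) {
    warning("constant input: correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(v), method = method))
  }
  ct <- suppressWarnings(stats::cor.test(v, a, method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(v), method = method)
}

#' Dichotomize clinical stage into early/late
#'
#' Stages I-II map to `"early"`, III-IV to `"late"`; other values give `NA`.
#'
#' @param stage character/factor vector of stages.
#' @return factor with levels `early`, `late`.
#' @export
stage_early_late <- function(stage) {
  s <- as.character(stage)
  out <- ifelse(s %in% c("I", "II"), "early", ifelse(s %in% c("III", "IV"), "late", NA))
  factor(out, levels = c("early", "late"))
}

#' Dichotomize age at the sample median
#'
#' The split point is the median of the ages at hand (never a hard-coded
#' year); ties at the median fall in the upper group.
#'
#' @param ages numeric vector.
#' @return list: `group` (factor `"<median"` / `">=median"`), `median`.
#' @export
age_median_split <- function(ages) {
  med <- stats::median(ages, na.rm = TRUE)
  g <- factor(ifelse(ages < med, "<median", ">=median"),
              levels = c("<median", ">=median"))
  list(group = g, median = med)
}
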