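# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' All stochastic stages (simulation, partitioning, forests, cross-validation
#' folds, permutations, bootstrap) draw their seed from one master seed through
#' this function, so a full pipeline run is replayable stage by stage.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"partition"` or `"forest"`.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(abs(master)) %% m
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1L) + 1L)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even (87.25 -> 87.2); reported clinical
#' percentages here use the conventional half-away-from-zero rule
#' (87.25 -> 87.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stratified holdout: total test size is ceiling(fraction * n), allocated to
# classes by largest remainder (ties resolved toward the earlier factor level).
# Returns integer indices of the TEST set.
stratified_test_indices <- function(labels, test_fraction, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  n_test <- ceiling(test_fraction * n)
  tab <- table(labels)
  quota <- n_test * as.numeric(tab) / n
  base <- floor(quota)
  rem <- quota - base
  extra <- n_test - sum(base)
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem)) # largest remainder, then level order
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  set.seed(seed)
  idx <- unlist(lapply(seq_along(tab), function(i) {
    pool <- which(labels == names(tab)[i])
    sample(pool, base[i])
  }), use.names = FALSE)
  sort(idx)
}

# coerce labels to a case/control factor; first level = case unless an explicit
# `case` level is given. Used by every two-class operation.
as_case_control <- function(labels, case = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2L) {
    stop("labels must contain exactly two classes, got ", nlevels(f), call. = FALSE)
  }
  if (!is.null(case)) {
    if (!case %in% levels(f)) stop("case level '", case, "' not found in labels", call. = FALSE)
    f <- stats::relevel(f, ref = case)
  }
  f
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
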