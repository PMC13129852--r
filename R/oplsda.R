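# Orthogonal projections to latent structures discriminant analysis (OPLS-DA)
# implemented from the NIPALS-style recursion for a single +/-1 response:
# class-orthogonal variation is deflated from X before the single predictive
# component is extracted, so the predictive score carries all the between-
# class variation and each orthogonal score is exactly uncorrelated with it.

opls_scale <- function(x, scaling) {
  ctr <- colMeans(x)
  scl <- switch(scaling,
                "unit-variance" = apply(x, 2, stats::sd),
                "pareto" = sqrt(apply(x, 2, stats::sd)),
                "none" = rep(1, ncol(x)))
  scl[!is.finite(scl)] <- 0
  list(center = ctr, scale = scl)
}

# core extraction on a prepared (centered/scaled) matrix; y centered +/-1
opls_core <- function(xs, yc, n_orthogonal) {
  W_o <- P_o <- NULL
  T_o <- NULL
  w <- drop(crossprod(xs, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  for (h in seq_len(n_orthogonal)) {
    t <- drop(xs %*% w)
    p <- drop(crossprod(xs, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(xs %*% w_o)
    p_o <- drop(crossprod(xs, t_o)) / sum(t_o^2)
    xs <- xs - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    # predictive weight re-estimated on the deflated matrix
    w <- drop(crossprod(xs, yc)) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
  }
  t <- drop(xs %*% w)
  p <- drop(crossprod(xs, t)) / sum(t^2)
  c_coef <- sum(yc * t) / sum(t^2)
  list(w = w, p = p, t = t, c = c_coef, W_o = W_o, P_o = P_o, T_o = T_o)
}

#' Fit an OPLS-DA model
#'
#' The two-class response is encoded +/-1 and centered; `n_orthogonal`
#' response-orthogonal components are removed from the (centered, scaled)
#' data before one predictive component is extracted. `R2Y_cum` is the
#' fraction of response variation explained on the training data.
#'
#' @param x samples x features numeric matrix, complete.
#' @param labels two-class labels; first level (or `case`) encodes +1.
#' @param n_orthogonal number of orthogonal components (>= 0), or `"auto"`
#'   to add components while cross-validated Q2 improves by more than 0.01.
#' @param scaling `"unit-variance"` (default), `"pareto"`, or `"none"`; mean
#'   centering always applies. Zero-variance features are dropped with a
#'   warning.
#' @param case optional case-level name.
#' @return list of class `opls_model` with weights/loadings/scores of the
#'   predictive component (`w, p, t, c`), the orthogonal components
#'   (`W_o, P_o, T_o`), centering/scaling vectors, `R2Y_cum` and bookkeeping.
#' @export
fit_oplsda <- function(x, labels, n_orthogonal = 1,
                       scaling = c("unit-variance", "pareto", "none"),
                       case = NULL) {
  scaling <- match.arg(scaling)
  y <- as_case_control(labels, case)
  if (identical(n_orthogonal, "auto")) {
    n_orthogonal <- auto_n_orthogonal(x, y, scaling)
  }
  stopifnot(n_orthogonal >= 0)
  if (nrow(x) <= n_orthogonal + 1) stop("need n_samples > n_orthogonal + 1", call. = FALSE)
  sc <- opls_scale(x, scaling)
  drop_ft <- sc$scale == 0
  if (any(drop_ft)) {
    warning(sum(drop_ft), " zero-variance feature(s) dropped before scaling")
    x <- x[, !drop_ft, drop = FALSE]
    sc <- lapply(sc, function(v) v[!drop_ft])
  }
  xs <- sweep(sweep(x, 2, sc$center), 2, ifelse(sc$scale == 0, 1, sc$scale), "/")
  yv <- ifelse(y == levels(y)[1], 1, -1)
  yc <- yv - mean(yv)
  core <- opls_core(xs, yc, n_orthogonal)
  yhat <- core$t * core$c
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  structure(c(core, list(center = sc$center, scale = sc$scale,
                         scaling = scaling, y_mean = mean(yv),
                         classes = levels(y), R2Y_cum = r2y,
                         n_orthogonal = if (is.null(core$T_o)) 0L else ncol(core$T_o),
                         kept = which(!drop_ft),
                         feature_ids = colnames(x))),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("opls_model: 1 predictive + ", x$n_orthogonal, " orthogonal component(s), ",
      length(x$w), " features; R2Y(cum) = ", round(x$R2Y_cum, 4), "\n", sep = "")
  invisible(x)
}

#' Predict the continuous class score of new samples
#'
#' Applies the training centering/scaling, strips the stored orthogonal
#' components, and projects on the predictive component. Scores above 0 map
#' to the first class.
#'
#' @param object an `opls_model`.
#' @param newdata samples x features matrix over the model's features.
#' @param ... unused.
#' @return data.frame `score` (predicted centered response), `t_pred`
#'   (predictive score) and `class`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  if (!is.null(object$feature_ids) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  } else if (ncol(newdata) != length(object$w)) {
    newdata <- newdata[, object$kept, drop = FALSE]
  }
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              ifelse(object$scale == 0, 1, object$scale), "/")
  if (!is.null(object$W_o)) {
    for (h in seq_len(ncol(object$W_o))) {
      t_o <- drop(xs %*% object$W_o[, h])
      xs <- xs - tcrossprod(t_o, object$P_o[, h])
    }
  }
  t_pred <- drop(xs %*% object$w)
  score <- t_pred * object$c
  data.frame(score = score, t_pred = t_pred,
             class = ifelse(score + object$y_mean >= 0, object$classes[1],
                            object$classes[2]),
             stringsAsFactors = FALSE)
}

make_stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (lv in levels(y)) {
    ix <- sample(which(y == lv))
    f[ix] <- rep(seq_len(folds), length.out = length(ix))
  }
  # every fold must contain both classes; refold smaller if not
  tabs <- table(factor(f, levels = seq_len(folds)), y)
  if (any(tabs == 0)) {
    warning("a fold lost a class; refolding with ", folds - 1, " folds")
    return(make_stratified_folds(y, folds - 1, seed + 1))
  }
  f
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Stratified k-fold cross-validation: each fold is predicted by a model fit
#' on the remaining folds and `Q2 = 1 - PRESS/TSS` over the pooled held-out
#' predictions of the centered +/-1 response.
#'
#' @inheritParams fit_oplsda
#' @param folds number of folds (default 7, the convention of mainstream
#'   OPLS tools).
#' @param seed integer seed fixing the fold assignment.
#' @return list `Q2`, `press`, `tss`, `folds`, `fold_assignment`, `yhat`
#'   (per-sample held-out predicted response on the +/-1 scale).
#' @export
cross_validate_q2 <- function(x, labels, folds = 7, n_orthogonal = 1,
                              scaling = c("unit-variance", "pareto", "none"),
                              case = NULL, seed = 1) {
  scaling <- match.arg(scaling)
  y <- as_case_control(labels, case)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (nlevels(y) < 2) stop("both classes required", call. = FALSE)
  fa <- make_stratified_folds(y, folds, derive_seed(seed, "cvfolds"))
  yv <- ifelse(y == levels(y)[1], 1, -1)
  press <- 0
  yc_all <- yv - mean(yv)
  yhat <- numeric(length(yv))
  for (k in sort(unique(fa))) {
    tr <- fa != k
    fit <- fit_oplsda(x[tr, , drop = FALSE], y[tr], n_orthogonal, scaling,
                      case = levels(y)[1])
    pr <- predict.opls_model(fit, x[!tr, , drop = FALSE])
    # held-out response centered with the training mean, as at prediction time
    press <- press + sum((yv[!tr] - fit$y_mean - pr$score)^2)
    yhat[!tr] <- pr$score + fit$y_mean
  }
  tss <- sum(yc_all^2)
  list(Q2 = 1 - press / tss, press = press, tss = tss,
       folds = length(unique(fa)), fold_assignment = fa, yhat = yhat)
}

auto_n_orthogonal <- function(x, y, scaling, max_orth = 5, seed = 1) {
  best <- cross_validate_q2(x, y, n_orthogonal = 0, scaling = scaling, seed = seed)$Q2
  n_o <- 0
  while (n_o < max_orth) {
    q2 <- cross_validate_q2(x, y, n_orthogonal = n_o + 1, scaling = scaling, seed = seed)$Q2
    if (q2 - best <= 0.01) break
    best <- q2; n_o <- n_o + 1
  }
  n_o
}

#' Label-permutation test for an OPLS-DA statistic
#'
#' Reshuffles the class labels `n_perm` times, recomputes the statistic (Q2
#' by default, or training R2Y), and reports the plus-one estimator
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)`, which is never zero.
#'
#' @inheritParams cross_validate_q2
#' @param n_perm number of permutations (default 100).
#' @param statistic `"Q2"` (default) or `"R2Y"`.
#' @return list of class `opls_permutation`: `p`, `observed`, `null`
#'   (permuted statistics), `n_perm`, `statistic`.
#' @export
permutation_test <- function(x, labels, n_perm = 100, statistic = c("Q2", "R2Y"),
                             folds = 7, n_orthogonal = 1,
                             scaling = c("unit-variance", "pareto", "none"),
                             case = NULL, seed = 1) {
  statistic <- match.arg(statistic)
  scaling <- match.arg(scaling)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  y <- as_case_control(labels, case)
  stat_fun <- function(yy, s) {
    if (statistic == "Q2") {
      cross_validate_q2(x, yy, folds, n_orthogonal, scaling, seed = s)$Q2
    } else {
      suppressWarnings(fit_oplsda(x, yy, n_orthogonal, scaling)$R2Y_cum)
    }
  }
  observed <- stat_fun(y, derive_seed(seed, "obs"))
  set.seed(derive_seed(seed, "perm"))
  perms <- lapply(seq_len(n_perm), function(b) sample(y)) # drawn up front so
  # the internal fold seeding below cannot disturb the permutation stream
  null <- vapply(seq_len(n_perm), function(b) {
    stat_fun(perms[[b]], derive_seed(seed, paste0("permcv", b)))
  }, numeric(1))
  structure(list(p = (1 + sum(null >= observed)) / (1 + n_perm),
                 observed = observed, null = null, n_perm = n_perm,
                 statistic = statistic),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat("permutation test (", x$statistic, "): observed = ", round(x$observed, 4),
      ", p = ", signif(x$p, 4), " over ", x$n_perm, " permutations\n", sep = "")
  invisible(x)
}
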