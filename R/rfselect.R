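# Stage-one feature prioritization: the feature space is randomly partitioned
# into disjoint subsets, each subset is ranked independently by random-forest
# Gini importance on a stratified training split, and the per-subset top
# fractions are aggregated into a consensus candidate set. A repeat-and-
# require-support (stability) mode re-runs the whole pass over fresh
# partitions and keeps features selected in at least `min_support` runs.

#' Random-forest ranking configuration
#'
#' @param n_trees trees per forest (default 20, chosen for stable importance
#'   rankings at low cost).
#' @param train_fraction fraction of samples in the stratified training split
#'   (default 0.70; the held-out share is `ceiling((1 - train_fraction) * n)`
#'   samples).
#' @param cv_folds folds for internal hyperparameter tuning (default 5).
#' @param seed integer seed controlling the split and the forests.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 20, train_fraction = 0.70, cv_folds = 5, seed = 1) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  structure(list(n_trees = as.integer(n_trees), train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "rf_config")
}

#' Partition the feature space into disjoint random subsets
#'
#' @param n_features total number of features.
#' @param k number of subsets (default 10); subset sizes differ by at most 1.
#' @param seed integer seed.
#' @return list of class `subspace_partition` with `k`, `assignment`
#'   (feature index -> subset index) and `seed`.
#' @export
partition_feature_space <- function(n_features, k = 10, seed = 1) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n_features) stop("k (", k, ") exceeds n_features (", n_features, ")", call. = FALSE)
  set.seed(as.integer(seed))
  assignment <- sample(rep(seq_len(k), length.out = n_features))
  structure(list(k = as.integer(k), assignment = assignment, seed = as.integer(seed)),
            class = "subspace_partition")
}

# Stratified training indices for an rf_config (complement of the ceiling-
# sized test set, so e.g. 287 samples at 0.70 train -> 87 held out).
rf_train_indices <- function(labels, config) {
  test <- stratified_test_indices(labels, 1 - config$train_fraction,
                                  seed = derive_seed(config$seed, "split"))
  setdiff(seq_along(labels), test)
}

#' Rank one feature subset by random-forest Gini importance
#'
#' Fits a classification forest on the stratified training split of the given
#' subset and returns each feature's mean decrease in Gini impurity and its
#' within-subset rank (1 = most important). Forests use bootstrap resampling,
#' the Gini split criterion, sqrt(p) candidate features per split, unlimited
#' depth and minimum leaf size 1.
#'
#' @param x numeric matrix (samples x features of one subset), complete.
#' @param labels two-class factor/vector aligned with rows of `x`.
#' @param config an [rf_config()].
#' @param subset_index integer tag recorded in the output.
#' @return data.frame `feature_id, subset, importance, rank`.
#' @export
rank_subset_features <- function(x, labels, config = rf_config(), subset_index = 1L) {
  y <- as_case_control(labels)
  if (min(table(y)) < 2) stop("both classes need >= 2 samples", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  tr <- rf_train_indices(y, config)
  if (nlevels(droplevels(y[tr])) < 2) stop("training split lost a class", call. = FALSE)
  d <- data.frame(..y.. = y[tr], x[tr, , drop = FALSE], check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "..y..", data = d,
    num.trees = config$n_trees, importance = "impurity",
    mtry = max(1L, floor(sqrt(ncol(x)))), min.node.size = 1,
    seed = derive_seed(config$seed, paste0("forest", subset_index)),
    num.threads = 1
  )
  imp <- fit$variable.importance[colnames(x)]
  imp[!is.finite(imp)] <- 0
  imp <- pmax(imp, 0)
  data.frame(feature_id = colnames(x), subset = as.integer(subset_index),
             importance = as.numeric(imp),
             rank = rank(-imp, ties.method = "first"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank every subset of a partition
#'
#' @param x numeric matrix (samples x all features), complete; column names
#'   are feature ids.
#' @param labels two-class labels.
#' @param partition a [partition_feature_space()] result over `ncol(x)`.
#' @param config an [rf_config()].
#' @return data.frame of stacked [rank_subset_features()] fragments.
#' @export
rank_all_subsets <- function(x, labels, partition, config = rf_config()) {
  stopifnot(length(partition$assignment) == ncol(x))
  out <- lapply(seq_len(partition$k), function(s) {
    fi <- which(partition$assignment == s)
    rank_subset_features(x[, fi, drop = FALSE], labels, config, subset_index = s)
  })
  do.call(rbind, out)
}

#' Aggregate per-subset rankings into a consensus feature set
#'
#' Within each subset the top `ceil(top_fraction * subset size)` features by
#' importance are flagged; the consensus set is their union. The default
#' `top_fraction = 0.007` reproduces the conventional candidate-set scale of
#' roughly 1000 features out of ~147k.
#'
#' @param fragments data.frame from [rank_all_subsets()] (or rbound
#'   [rank_subset_features()] fragments, one subset per feature).
#' @param top_fraction fraction of each subset to flag, in (0, 1].
#' @return list of class `feature_ranking`: `ranking` (the fragments with a
#'   logical `selected` column), `consensus` (selected feature ids) and
#'   `n_selected`.
#' @export
select_consensus_features <- function(fragments, top_fraction = 0.007) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(fragments$feature_id)) {
    stop("each feature must be ranked in exactly one subset", call. = FALSE)
  }
  sel <- unlist(lapply(split(fragments, fragments$subset), function(fr) {
    ntop <- ceiling(top_fraction * nrow(fr))
    fr$feature_id[fr$rank <= ntop]
  }), use.names = FALSE)
  fragments$selected <- fragments$feature_id %in% sel
  structure(list(ranking = fragments, consensus = sel,
                 n_selected = length(sel), top_fraction = top_fraction),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking: ", nrow(x$ranking), " features in ",
      length(unique(x$ranking$subset)), " subsets; consensus set: ",
      x$n_selected, " (top fraction ", x$top_fraction, ")\n", sep = "")
  invisible(x)
}

#' One full subspace selection pass
#'
#' Convenience wrapper: partition, rank every subset, aggregate.
#'
#' @param x samples x features matrix, complete, with feature-id column
#'   names.
#' @param labels two-class labels.
#' @param k number of subsets.
#' @param top_fraction per-subset selection fraction.
#' @param config an [rf_config()]; its seed drives the partition and forests.
#' @return A `feature_ranking` (see [select_consensus_features()]).
#' @export
subspace_select <- function(x, labels, k = 10, top_fraction = 0.007,
                            config = rf_config()) {
  part <- partition_feature_space(ncol(x), k, seed = derive_seed(config$seed, "partition"))
  frags <- rank_all_subsets(x, labels, part, config)
  select_consensus_features(frags, top_fraction)
}

#' Stability (repeat-and-require-support) consensus selection
#'
#' Runs [subspace_select()] `n_runs` times over fresh partitions, training
#' splits and forests, and keeps features selected in at least `min_support`
#' runs. `min_support = 1` is the union over runs; higher values demand
#' cross-run reproducibility.
#'
#' @inheritParams subspace_select
#' @param n_runs number of independent repartition runs.
#' @param min_support minimum number of runs a feature must be selected in.
#' @return list: `consensus` (feature ids), `support` (named integer vector,
#'   selections per feature over runs), `n_runs`, `min_support`.
#' @export
subspace_select_stable <- function(x, labels, k = 10, top_fraction = 0.007,
                                   config = rf_config(), n_runs = 10,
                                   min_support = 1) {
  stopifnot(n_runs >= 1, min_support >= 1, min_support <= n_runs)
  support <- stats::setNames(integer(ncol(x)), colnames(x))
  for (r in seq_len(n_runs)) {
    cfg_r <- rf_config(config$n_trees, config$train_fraction, config$cv_folds,
                       seed = derive_seed(config$seed, paste0("stab", r)))
    sel <- subspace_select(x, labels, k, top_fraction, cfg_r)$consensus
    support[sel] <- support[sel] + 1L
  }
  list(consensus = names(support)[support >= min_support],
       support = support, n_runs = n_runs, min_support = min_support)
}

#' Evaluate a consensus feature set by a refit forest
#'
#' Refits a forest on the stratified 70% training split restricted to the
#' consensus features and reports the confusion matrix, accuracy and F1 on
#' the held-out 30% (test size = `ceiling(0.3 * n)`, so 287 samples give an
#' 87-sample test set).
#'
#' @param x samples x features matrix restricted to the consensus features.
#' @param labels two-class labels; the first level (or `case`) is the
#'   positive class.
#' @param config an [rf_config()].
#' @param case optional name of the positive-class level.
#' @return A [metric_report()] computed on the held-out split, with the
#'   held-out predictions attached as attributes `predictions` and
#'   `test_indices`.
#' @export
evaluate_feature_set <- function(x, labels, config = rf_config(), case = NULL) {
  if (ncol(x) == 0) stop("consensus feature set is empty", call. = FALSE)
  y <- as_case_control(labels, case)
  tr <- rf_train_indices(y, config)
  te <- setdiff(seq_along(y), tr)
  d <- data.frame(..y.. = y[tr], x[tr, , drop = FALSE], check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "..y..", data = d,
    num.trees = config$n_trees, mtry = max(1L, floor(sqrt(ncol(x)))),
    min.node.size = 1, seed = derive_seed(config$seed, "evalforest"),
    num.threads = 1
  )
  pred <- stats::predict(fit, data.frame(x[te, , drop = FALSE], check.names = FALSE))$predictions
  rep <- classification_metrics(pred, y[te], case = levels(y)[1])
  attr(rep, "predictions") <- pred
  attr(rep, "test_indices") <- te
  rep
}

#' Tune the per-subset selection fraction by cross-validation
#'
#' Grid-searches `top_fraction` with stratified `config$cv_folds`-fold
#' cross-validation confined to the training samples: for each fold, a
#' selection pass runs on the in-fold data and a refit forest is scored on
#' the held-out fold. The candidate with the highest mean held-out accuracy
#' wins; ties go to the smaller (sparser) fraction. Validation data must
#' never enter this routine.
#'
#' @param x samples x features matrix (training cohort only), complete.
#' @param labels two-class labels.
#' @param candidates candidate top fractions.
#' @param k number of feature subsets per pass.
#' @param config an [rf_config()].
#' @return list: `best` (chosen fraction), `accuracy` (named mean held-out
#'   accuracy per candidate).
#' @export
tune_top_fraction <- function(x, labels, candidates = c(0.005, 0.007, 0.01, 0.02),
                              k = 10, config = rf_config()) {
  y <- as_case_control(labels)
  folds <- make_stratified_folds(y, config$cv_folds, derive_seed(config$seed, "tune"))
  acc <- sapply(sort(candidates), function(tf) {
    mean(vapply(sort(unique(folds)), function(fd) {
      tr <- folds != fd
      cfg <- rf_config(config$n_trees, config$train_fraction, config$cv_folds,
                       seed = derive_seed(config$seed, paste0("tune", fd)))
      sel <- subspace_select(x[tr, , drop = FALSE], y[tr], k, tf, cfg)$consensus
      d <- data.frame(..y.. = y[tr], x[tr, sel, drop = FALSE], check.names = FALSE)
      fit <- ranger::ranger(dependent.variable.name = "..y..", data = d,
                            num.trees = cfg$n_trees, min.node.size = 1,
                            seed = derive_seed(cfg$seed, "tunefit"), num.threads = 1)
      pr <- stats::predict(fit, data.frame(x[!tr, sel, drop = FALSE],
                                           check.names = FALSE))$predictions
      mean(pr == y[!tr])
    }, numeric(1)))
  })
  names(acc) <- as.character(sort(candidates))
  list(best = sort(candidates)[which.max(acc)], accuracy = acc)
}
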