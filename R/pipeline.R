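# End-to-end orchestration: simulate -> process -> select -> triage -> panel
# -> report, with a manifest recording inputs, parameters, seed and output
# checksums so a rerun with the same configuration is byte-identical.

#' Assemble a pipeline run configuration
#'
#' Collects every stage parameter with its conventional default: the
#' minimum-height threshold (30000), QC CV bound (15%), MS1/MS2 annotation
#' tolerances (0.01 / 0.025 Da) and identification score (80%), ten feature
#' subsets, 20 trees, 70% training fraction, AUC triage at > 0.90, and 100
#' permutations for the OPLS-DA validation.
#'
#' @param peak_table,meta,qc_table,annotation_reference,concentrations input
#'   file paths (those a stage needs must exist at run time).
#' @param out_dir output directory.
#' @param min_height,cv_max,k_subsets,n_trees,train_fraction,top_fraction,
#'   auc_threshold,ms1_tol,ms2_tol,score_min,n_permutations,n_orthogonal,
#'   cv_folds stage parameters (see the stage functions).
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @param panel_mode `"discovery-train"` or `"validation-split"`.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it via [derive_seed()].
#' @return list of class `run_config`.
#' @export
run_config <- function(peak_table = NULL, meta = NULL, qc_table = NULL,
                       annotation_reference = NULL, concentrations = NULL,
                       out_dir = "metabopanel_out",
                       min_height = 30000, cv_max = 0.15,
                       k_subsets = 10, n_trees = 20, train_fraction = 0.70,
                       top_fraction = 0.007, auc_threshold = 0.90,
                       ms1_tol = 0.01, ms2_tol = 0.025, score_min = 0.80,
                       n_permutations = 100, n_orthogonal = 1, cv_folds = 5,
                       ci_method = "wilson",
                       panel_mode = "discovery-train",
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$top_fraction > 0, cfg$top_fraction <= 1,
            cfg$auc_threshold >= 0.5, cfg$auc_threshold < 1,
            cfg$n_permutations >= 1, cfg$k_subsets >= 1)
  class(cfg) <- "run_config"
  cfg
}

config_params <- function(config) {
  config[setdiff(names(config), c("peak_table", "meta", "qc_table",
                                  "annotation_reference", "concentrations",
                                  "out_dir"))]
}

write_manifest <- function(config, inputs, outputs, path) {
  manifest <- list(
    inputs = lapply(inputs[!vapply(inputs, is.null, logical(1))], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = config_params(config),
    seed = config$seed,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

pipeline_abort <- function(stage, code, msg) {
  stop(sprintf("[stage:%s] [%s] %s", stage, code, msg), call. = FALSE)
}

#' Run the discovery stage end to end
#'
#' Reads the aligned peak table, metadata and QC table; applies the
#' processing chain (minimum height, internal-standard normalization, QC CV
#' filter, imputation); runs random-subspace random-forest consensus
#' selection and evaluates the consensus set on the held-out split; computes
#' volcano statistics and per-feature AUCs over the consensus features;
#' triages at the AUC threshold; annotates the triaged features when a
#' reference is given; fits the OPLS-DA model with cross-validated Q2 and a
#' label-permutation test. All stage outputs are written as CSV/JSON plus a
#' manifest with checksums; a rerun with the same config is byte-identical.
#'
#' @param config a [run_config()] with at least `peak_table` and `meta`
#'   paths set.
#' @return (invisibly) list with the in-memory stage results: `ranking`,
#'   `consensus`, `evaluation`, `volcano`, `auc_table`, `retained`,
#'   `annotations`, `opls`, `funnel`, `paths`.
#' @export
run_discovery <- function(config) {
  for (f in c("peak_table", "meta")) {
    if (is.null(config[[f]])) pipeline_abort("input", "E_CONFIG", paste0("config$", f, " not set"))
    if (!file.exists(config[[f]])) {
      pipeline_abort("input", "E_MISSING_FILE", paste0(f, " not found: ", config[[f]]))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("[discovery] reading inputs")
  fm <- read_peak_table(config$peak_table)
  meta <- utils::read.csv(config$meta, stringsAsFactors = FALSE)
  if (!all(rownames(fm$intensities) %in% meta$sample_id)) {
    pipeline_abort("input", "E_META", "peak-table samples missing from metadata")
  }
  meta <- meta[match(rownames(fm$intensities), meta$sample_id), ]
  labels <- factor(meta$group, levels = c("case", "control"))
  funnel <- c(features_in = ncol(fm$intensities))

  fm <- filter_min_height(fm, config$min_height)
  funnel["after_min_height"] <- ncol(fm$intensities)

  is_ids <- fm$features$feature_id[fm$features$is_standard]
  if (length(is_ids) == 3) {
    fm <- normalize_internal_standards(fm, internal_standard_set(is_ids))
  } else {
    message("[discovery] internal standards not found (", length(is_ids),
            " flagged); skipping IS normalization")
  }

  if (!is.null(config$qc_table)) {
    if (!file.exists(config$qc_table)) {
      pipeline_abort("qc", "E_MISSING_FILE", paste0("qc_table not found: ", config$qc_table))
    }
    qc <- read_peak_table(config$qc_table)
    fm <- filter_qc_cv(fm, qc, config$cv_max)
  }
  funnel["after_qc_cv"] <- ncol(fm$intensities)

  fm <- impute_missing(fm)

  # selection matrix excludes the internal standards
  keep <- !fm$features$is_standard
  x <- fm$intensities[, keep, drop = FALSE]
  message("[discovery] subspace random-forest selection over ", ncol(x), " features")
  cfg_rf <- rf_config(config$n_trees, config$train_fraction, config$cv_folds,
                      seed = derive_seed(config$seed, "rfselect"))
  ranking <- subspace_select(x, labels, k = config$k_subsets,
                             top_fraction = config$top_fraction, config = cfg_rf)
  funnel["consensus"] <- ranking$n_selected
  evaluation <- evaluate_feature_set(x[, ranking$consensus, drop = FALSE], labels,
                                     cfg_rf, case = "case")

  vol <- volcano(x[, ranking$consensus, drop = FALSE], labels, case = "case")
  auc_tab <- data.frame(
    feature_id = ranking$consensus,
    auc = vapply(ranking$consensus, function(f) feature_auc(x[, f], labels, case = "case")$auc,
                 numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  retained <- auc_filter(stats::setNames(auc_tab$auc, auc_tab$feature_id),
                         config$auc_threshold)
  funnel["auc_retained"] <- length(retained)

  annotations <- NULL
  if (!is.null(config$annotation_reference)) {
    if (!file.exists(config$annotation_reference)) {
      pipeline_abort("annotation", "E_MISSING_FILE",
                     paste0("annotation_reference not found: ", config$annotation_reference))
    }
    ref <- read_annotation_reference(config$annotation_reference)
    ft <- fm$features[fm$features$feature_id %in% retained, , drop = FALSE]
    annotations <- annotate_features(ft, ref, config$ms1_tol, config$ms2_tol,
                                     config$score_min)
    funnel["annotated_accepted"] <- sum(annotations$accepted)
  }

  message("[discovery] OPLS-DA on the consensus features")
  xc <- x[, ranking$consensus, drop = FALSE]
  opls <- suppressWarnings(fit_oplsda(xc, labels, n_orthogonal = config$n_orthogonal,
                                      case = "case"))
  q2 <- suppressWarnings(cross_validate_q2(xc, labels, n_orthogonal = config$n_orthogonal,
                                           case = "case",
                                           seed = derive_seed(config$seed, "oplscv")))
  perm <- suppressWarnings(permutation_test(xc, labels, n_perm = config$n_permutations,
                                            n_orthogonal = config$n_orthogonal,
                                            case = "case",
                                            seed = derive_seed(config$seed, "oplsperm")))

  message("[discovery] feature funnel: ",
          paste(names(funnel), funnel, sep = "=", collapse = " -> "))

  paths <- c(ranking = file.path(config$out_dir, "feature_ranking.csv"),
             volcano = file.path(config$out_dir, "volcano.csv"),
             auc = file.path(config$out_dir, "feature_auc.csv"),
             evaluation = file.path(config$out_dir, "consensus_evaluation.json"),
             opls = file.path(config$out_dir, "opls_summary.json"),
             scores = file.path(config$out_dir, "opls_scores.csv"))
  utils::write.csv(ranking$ranking, paths[["ranking"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(vol, paths[["volcano"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(auc_tab, retained = auc_tab$feature_id %in% retained),
                   paths[["auc"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(counts = as.list(evaluation$counts),
                            accuracy_pct = evaluation$accuracy_pct,
                            f1_pct = evaluation$f1_pct,
                            funnel = as.list(funnel)),
                       paths[["evaluation"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(R2Y_cum = opls$R2Y_cum, Q2_cum = q2$Q2,
                            n_orthogonal = opls$n_orthogonal,
                            permutation_p = perm$p, n_perm = perm$n_perm,
                            statistic = perm$statistic),
                       paths[["opls"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(sample_id = rownames(xc), group = as.character(labels),
                              t_pred = opls$t,
                              t_orth1 = if (opls$n_orthogonal > 0) opls$T_o[, 1] else NA),
                   paths[["scores"]], row.names = FALSE, quote = FALSE)
  if (!is.null(annotations)) {
    paths["annotations"] <- file.path(config$out_dir, "annotations.csv")
    utils::write.csv(annotations, paths[["annotations"]], row.names = FALSE, quote = FALSE)
  }
  manifest <- file.path(config$out_dir, "manifest.json")
  write_manifest(config,
                 inputs = config[c("peak_table", "meta", "qc_table", "annotation_reference")],
                 outputs = paths, path = manifest)
  invisible(list(ranking = ranking, consensus = ranking$consensus,
                 evaluation = evaluation, volcano = vol, auc_table = auc_tab,
                 retained = retained, annotations = annotations,
                 opls = list(model = opls, q2 = q2, permutation = perm),
                 funnel = funnel, paths = c(paths, manifest = manifest)))
}

#' Apply a fitted panel to a validation cohort
#'
#' Applies the panel model without retraining (its coefficients as fitted),
#' computes the full metric report with confidence intervals, per-metabolite
#' AUCs and Youden cutoffs, and the standard stratified analyses (early/late
#' stage, sex, median-split age, tumor site) plus the ordered stage trend
#' test per metabolite. Outputs are written as CSV/JSON with a manifest.
#'
#' @param config a [run_config()] with `concentrations` and `meta` paths set
#'   (CSV; concentrations must carry the model's metabolite columns).
#' @param model a [fit_logistic_panel()] result.
#' @return (invisibly) list: `metrics`, `probabilities`, `per_metabolite`
#'   (AUC + cutoff per metabolite), `strata`, `trend`, `paths`.
#' @export
run_validation <- function(config, model) {
  for (f in c("concentrations", "meta")) {
    if (is.null(config[[f]])) pipeline_abort("input", "E_CONFIG", paste0("config$", f, " not set"))
    if (!file.exists(config[[f]])) {
      pipeline_abort("input", "E_MISSING_FILE", paste0(f, " not found: ", config[[f]]))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  conc <- utils::read.csv(config$concentrations, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!nrow(conc)) pipeline_abort("input", "E_EMPTY", "concentration table is empty")
  meta <- utils::read.csv(config$meta, stringsAsFactors = FALSE)
  meta <- meta[match(conc$sample_id, meta$sample_id), ]
  labels <- factor(meta$group, levels = c("case", "control"))
  miss <- setdiff(model$metabolites, names(conc))
  if (length(miss)) {
    pipeline_abort("panel", "E_COLUMNS", paste("metabolite column(s) absent:",
                                               paste(miss, collapse = ", ")))
  }
  prob <- predict_probability(model, conc)
  metrics <- classification_metrics(prob, labels, case = "case",
                                    ci_method = config$ci_method)

  per_met <- lapply(model$metabolites, function(mb) {
    v <- conc[[mb]]
    a <- auc_ci(v, labels, case = "case")
    cut <- youden_cutoff(v, labels, case = "case")
    trend <- tryCatch(stage_trend_test(v[labels == "case"], meta$stage[labels == "case"]),
                      error = function(e) NULL)
    strat <- list(
      stage = tryCatch(subgroup_compare(v, ifelse(labels == "control", "control",
                                                  as.character(stage_early_late(meta$stage)))),
                       error = function(e) NULL),
      sex = tryCatch(subgroup_compare(v[labels == "case"], meta$sex[labels == "case"]),
                     error = function(e) NULL),
      age = tryCatch(subgroup_compare(v[labels == "case"],
                                      age_median_split(meta$age[labels == "case"])$group),
                     error = function(e) NULL),
      site = tryCatch(subgroup_compare(v[labels == "case"], meta$site[labels == "case"]),
                      error = function(e) NULL)
    )
    list(metabolite = mb, auc = a, cutoff = cut, trend = trend, strata = strat)
  })
  names(per_met) <- model$metabolites

  per_tab <- do.call(rbind, lapply(per_met, function(r) data.frame(
    metabolite = r$metabolite, auc = r$auc$auc,
    auc_lo = r$auc$ci[1], auc_hi = r$auc$ci[2],
    cutoff = r$cutoff$cutoff, direction = r$cutoff$direction,
    sensitivity_pct = round_half_up(100 * r$cutoff$sensitivity, 1),
    specificity_pct = round_half_up(100 * r$cutoff$specificity, 1),
    trend_p = if (is.null(r$trend)) NA else r$trend$p,
    stringsAsFactors = FALSE, row.names = NULL)))

  paths <- c(metrics = file.path(config$out_dir, "panel_metrics.json"),
             probabilities = file.path(config$out_dir, "panel_probabilities.csv"),
             per_metabolite = file.path(config$out_dir, "per_metabolite.csv"))
  jsonlite::write_json(list(
    counts = as.list(metrics$counts),
    sensitivity_pct = metrics$sensitivity_pct,
    specificity_pct = metrics$specificity_pct,
    accuracy_pct = metrics$accuracy_pct,
    balanced_accuracy_pct = metrics$balanced_accuracy_pct,
    auc = metrics$auc$auc, auc_ci = as.list(stats::setNames(metrics$auc$ci, c("lower", "upper"))),
    ci = metrics$ci, ci_method = metrics$ci_method
  ), paths[["metrics"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(sample_id = conc$sample_id, group = as.character(labels),
                              probability = prob),
                   paths[["probabilities"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(per_tab, paths[["per_metabolite"]], row.names = FALSE, quote = FALSE)
  manifest <- file.path(config$out_dir, "validation_manifest.json")
  write_manifest(config, inputs = config[c("concentrations", "meta")],
                 outputs = paths, path = manifest)
  invisible(list(metrics = metrics, probabilities = prob,
                 per_metabolite = per_met, per_table = per_tab,
                 paths = c(paths, manifest = manifest)))
}
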