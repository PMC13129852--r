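# Synthetic-cohort generators. These emulate the structure of a two-cohort
# plasma metabolomics case/control study: log-normal feature intensities with
# a down-dominant planted marker set, three spiked internal standards, an
# age-confounded case group, pooled-QC replicate injections, and per-metabolite
# quantified concentrations for panel modeling. Every generator carries its
# ground truth so recovery can be scored.

#' Specify a synthetic untargeted cohort
#'
#' Defaults mirror the discovery-cohort structure of a case-control colorectal
#' cancer plasma study: 172 cases vs 115 controls, cases markedly older
#' (71 +/- 9.47 vs 40 +/- 12.08 years), a planted marker set that is
#' two-thirds downregulated in cases, and stage frequencies 28/47/60/37.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_features number of (non-standard) spectral features.
#' @param n_markers_down,n_markers_up planted markers lowered / raised in
#'   cases.
#' @param effect_log2fc_range interval the absolute per-marker log2 fold
#'   change is drawn from (uniform).
#' @param base_log_mean,base_log_sd hyper-distribution (log2 scale) of
#'   feature-specific baseline log-intensities.
#' @param noise_log_sd within-feature biological + technical spread on the
#'   log2 scale.
#' @param missing_rate missing-at-random fraction applied after effect
#'   injection.
#' @param missing_mode `"mar"` (default) or `"intensity"` (missingness
#'   probability decreasing with intensity, emulating detection-limit
#'   censoring).
#' @param qc_cv technical coefficient of variation of the internal-standard
#'   features.
#' @param age_case_mean,age_case_sd,age_control_mean,age_control_sd per-group
#'   age distributions in years (the case excess is deliberate: it gives the
#'   covariate-adjustment machinery a realistic confounded test bed).
#' @param male_frac_case,male_frac_control sex composition per group.
#' @param stage_probs length-4 probability vector over stages I-IV (cases
#'   only; controls carry no stage).
#' @param site_probs length-2 probability vector over primary sites
#'   colon/rectal (cases only).
#' @param seed integer RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 172, n_controls = 115,
                        n_features = 2000,
                        n_markers_down = 50, n_markers_up = 25,
                        effect_log2fc_range = c(2, 3),
                        base_log_mean = 17, base_log_sd = 2,
                        noise_log_sd = 0.5,
                        missing_rate = 0.05,
                        missing_mode = c("mar", "intensity"),
                        qc_cv = 0.05,
                        age_case_mean = 71, age_case_sd = 9.47,
                        age_control_mean = 40, age_control_sd = 12.08,
                        male_frac_case = 93 / 172, male_frac_control = 56 / 115,
                        stage_probs = c(28, 47, 60, 37) / 172,
                        site_probs = c(141, 27) / 168,
                        seed = 1) {
  spec <- list(n_cases = n_cases, n_controls = n_controls,
               n_features = n_features,
               n_markers_down = n_markers_down, n_markers_up = n_markers_up,
               effect_log2fc_range = effect_log2fc_range,
               base_log_mean = base_log_mean, base_log_sd = base_log_sd,
               noise_log_sd = noise_log_sd,
               missing_rate = missing_rate,
               missing_mode = match.arg(missing_mode),
               qc_cv = qc_cv,
               age_case_mean = age_case_mean, age_case_sd = age_case_sd,
               age_control_mean = age_control_mean, age_control_sd = age_control_sd,
               male_frac_case = male_frac_case, male_frac_control = male_frac_control,
               stage_probs = stage_probs, site_probs = site_probs,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid cohort_spec field '", field, "': ", msg, call. = FALSE)
  }
  for (f in c("n_cases", "n_controls", "n_features", "n_markers_down", "n_markers_up")) {
    chk(is.numeric(spec[[f]]) && length(spec[[f]]) == 1 && spec[[f]] >= 0 &&
          spec[[f]] == floor(spec[[f]]), f, "must be a nonnegative count")
  }
  chk(spec$n_markers_down + spec$n_markers_up <= spec$n_features,
      "n_markers_down", "markers exceed n_features")
  chk(length(spec$effect_log2fc_range) == 2 &&
        spec$effect_log2fc_range[1] <= spec$effect_log2fc_range[2],
      "effect_log2fc_range", "must be an ordered interval")
  chk(spec$missing_rate >= 0 && spec$missing_rate <= 1, "missing_rate", "must lie in [0, 1]")
  chk(spec$qc_cv >= 0, "qc_cv", "must be >= 0")
  chk(length(spec$stage_probs) == 4 && abs(sum(spec$stage_probs) - 1) < 1e-12 &&
        all(spec$stage_probs >= 0), "stage_probs", "must be a 4-vector summing to 1")
  chk(abs(sum(spec$site_probs) - 1) < 1e-12, "site_probs", "must sum to 1")
  invisible(spec)
}

# names/masses of the three spiked internal standards appended by the generator
is_feature_ids <- function() c("IS_phe_d2", "IS_cholic_d4", "IS_lysoPC19_0")

#' Generate a synthetic untargeted cohort with planted ground truth
#'
#' Feature intensities are log-normal (log2-normal) with feature-specific
#' baselines drawn from `N(base_log_mean, base_log_sd)` and within-feature
#' spread `noise_log_sd`. Planted markers are shifted in cases by a log2 fold
#' change drawn from `effect_log2fc_range` (negative for down markers). Three
#' internal-standard features with no biological effect and small technical
#' CV are appended. Ages are drawn per group, producing the deliberate
#' age-by-group confound; stages and sites are assigned to cases only.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{a [feature_matrix()] of `n_cases + n_controls` samples;}
#'     \item{meta}{data.frame `sample_id, group, cohort, age, sex, stage,
#'       site`;}
#'     \item{truth}{list `marker_ids`, `marker_indices`, `marker_directions`
#'       (+1 up / -1 down in cases), `marker_log2fc`.}
#'   }
#' @export
generate_untargeted_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  p <- spec$n_features
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  sample_id <- sprintf("%s_%03d", ifelse(group == "case", "CRC", "CTL"),
                       c(seq_len(spec$n_cases), seq_len(spec$n_controls)))

  mu <- stats::rnorm(p, spec$base_log_mean, spec$base_log_sd)
  logx <- matrix(stats::rnorm(n * p, 0, spec$noise_log_sd), n, p)
  logx <- sweep(logx, 2, mu, "+")

  n_mark <- spec$n_markers_down + spec$n_markers_up
  marker_idx <- if (n_mark > 0) sort(sample.int(p, n_mark)) else integer(0)
  dirs <- integer(0)
  lfc <- numeric(0)
  if (n_mark > 0) {
    dirs <- sample(rep(c(-1L, 1L), c(spec$n_markers_down, spec$n_markers_up)))
    lfc <- dirs * stats::runif(n_mark, spec$effect_log2fc_range[1],
                               spec$effect_log2fc_range[2])
    logx[group == "case", marker_idx] <-
      sweep(logx[group == "case", marker_idx, drop = FALSE], 2, lfc, "+")
  }
  x <- 2^logx

  if (spec$missing_rate > 0) {
    if (spec$missing_mode == "mar") {
      miss <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
    } else {
      # detection-limit flavored: low-intensity cells are likelier to drop out
      z <- scale(logx)
      pr <- stats::plogis(-z) * 2 * spec$missing_rate
      miss <- matrix(stats::runif(n * p) < pr, n, p)
    }
    x[miss] <- NA_real_
  }

  # internal standards: constant spike level, small technical CV, no effect
  is_log_level <- c(19.5, 18.5, 18.5)
  is_sd <- sqrt(log(1 + spec$qc_cv^2)) / log(2) # log2-scale sd giving CV = qc_cv
  isx <- sapply(is_log_level, function(l) 2^stats::rnorm(n, l, is_sd))
  colnames(isx) <- is_feature_ids()

  feat <- data.frame(
    feature_id = c(sprintf("F%05d", seq_len(p)), is_feature_ids()),
    mz = c(stats::runif(p, 80, 1000), 167.0915, 412.3127, 537.3794),
    rt = c(stats::runif(p, 0.5, 20), 3.2, 11.5, 16.8),
    is_standard = c(rep(FALSE, p), rep(TRUE, 3)),
    stringsAsFactors = FALSE
  )
  xi <- cbind(x, isx)
  rownames(xi) <- sample_id
  colnames(xi) <- feat$feature_id

  age <- ifelse(group == "case",
                stats::rnorm(n, spec$age_case_mean, spec$age_case_sd),
                stats::rnorm(n, spec$age_control_mean, spec$age_control_sd))
  age <- pmax(18, round(age))
  sex <- ifelse(stats::runif(n) < ifelse(group == "case", spec$male_frac_case,
                                         spec$male_frac_control),
                "male", "female")
  stage <- rep(NA_character_, n)
  stage[group == "case"] <- sample(c("I", "II", "III", "IV"), spec$n_cases,
                                   replace = TRUE, prob = spec$stage_probs)
  site <- rep(NA_character_, n)
  site[group == "case"] <- sample(c("colon", "rectal"), spec$n_cases,
                                  replace = TRUE, prob = spec$site_probs)
  meta <- data.frame(sample_id = sample_id, group = group, cohort = "discovery",
                     age = age, sex = sex, stage = stage, site = site,
                     stringsAsFactors = FALSE)

  list(matrix = feature_matrix(xi, feat),
       meta = meta,
       truth = list(marker_ids = feat$feature_id[marker_idx],
                    marker_indices = marker_idx,
                    marker_directions = dirs,
                    marker_log2fc = lfc))
}

#' Generate pooled-QC replicate injections
#'
#' Emulates repeated injections of a pooled reference sample: each feature's
#' pooled mean (mean of present intensities across study samples) is jittered
#' log-normally so the per-feature replicate CV is approximately `cv`.
#'
#' @param fm a [feature_matrix()] of study samples.
#' @param n_reps number of replicate injections (>= 2; triplicate is the
#'   conventional design).
#' @param cv target technical coefficient of variation (>= 0; 0 returns the
#'   pooled means exactly).
#' @param seed integer RNG seed.
#' @return A `feature_matrix` of `n_reps` QC samples over the same features.
#' @export
generate_qc_replicates <- function(fm, n_reps = 3, cv = 0.10, seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  pooled <- colMeans(fm$intensities, na.rm = TRUE)
  p <- length(pooled)
  if (cv == 0) {
    q <- matrix(rep(pooled, each = n_reps), n_reps, p)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    # mean-preserving log-normal jitter: E[exp(N(-s^2/2, s))] = 1
    q <- matrix(pooled, n_reps, p, byrow = TRUE) *
      exp(matrix(stats::rnorm(n_reps * p, -sdlog^2 / 2, sdlog), n_reps, p))
  }
  rownames(q) <- sprintf("QC_%02d", seq_len(n_reps))
  colnames(q) <- fm$features$feature_id
  feature_matrix(q, fm$features)
}

#' Default five-metabolite panel concentration specification
#'
#' Group-wise concentration summaries (mean +/- sd, native units) of the five
#' quantified panel metabolites in a validation cohort; all five are lower in
#' cases than in controls.
#'
#' @return data.frame with columns `name, unit, case_mean, case_sd,
#'   control_mean, control_sd, family`.
#' @export
default_panel_spec <- function() {
  data.frame(
    name = c("N-methylcytisine", "2-piperidone", "theophylline",
             "dl-norleucine", "linolenic acid"),
    unit = c("ng/mL", "ng/mL", "ug/mL", "ug/mL", "ug/mL"),
    case_mean = c(4.15, 542.14, 23.00, 97.05, 3.91),
    case_sd = c(1.15, 111.00, 8.04, 10.03, 0.55),
    control_mean = c(7.82, 3963.58, 446.40, 215.38, 73.88),
    control_sd = c(1.81, 397.87, 44.08, 113.00, 17.00),
    family = "lognormal",
    stringsAsFactors = FALSE
  )
}

#' Generate quantified panel concentrations
#'
#' Draws per-metabolite concentrations per group from a moment-matched
#' log-normal (default; guarantees nonnegativity and the specified group mean
#' and sd) or a zero-truncated normal. `sd = 0` yields the group mean exactly.
#'
#' @param pspec data.frame as returned by [default_panel_spec()]; `family`
#'   may be `"lognormal"` or `"truncnorm"` per metabolite.
#' @param n_cases,n_controls group sizes (each >= 2).
#' @param seed integer RNG seed.
#' @param cohort cohort label written into the metadata.
#' @return list with `concentrations` (data.frame `sample_id` + one column
#'   per metabolite), `meta` (validation-cohort style sample metadata), and
#'   `units` (named character).
#' @export
generate_panel_concentrations <- function(pspec, n_cases, n_controls, seed = 1,
                                          cohort = "validation") {
  stopifnot(is.data.frame(pspec),
            all(c("name", "case_mean", "case_sd", "control_mean", "control_sd") %in% names(pspec)))
  if (n_cases < 2 || n_controls < 2) stop("need >= 2 samples per group", call. = FALSE)
  if (any(pspec$case_sd < 0 | pspec$control_sd < 0)) {
    stop("invalid panel spec: negative sd", call. = FALSE)
  }
  if (any(pspec$case_mean <= 0 | pspec$control_mean <= 0)) {
    stop("invalid panel spec: means must be > 0", call. = FALSE)
  }
  if (!"family" %in% names(pspec)) pspec$family <- "lognormal"
  if (!"unit" %in% names(pspec)) pspec$unit <- NA_character_
  set.seed(as.integer(seed))
  n <- n_cases + n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  sample_id <- sprintf("%s_V%03d", ifelse(group == "case", "CRC", "CTL"),
                       c(seq_len(n_cases), seq_len(n_controls)))

  draw <- function(m, s, k, family) {
    if (s == 0) return(rep(m, k))
    if (family == "lognormal") {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(k, meanlog, sdlog)
    } else { # zero-truncated normal by inverse-cdf
      a <- stats::pnorm(0, m, s)
      stats::qnorm(a + stats::runif(k) * (1 - a), m, s)
    }
  }
  conc <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pspec))) {
    v <- numeric(n)
    v[group == "case"] <- draw(pspec$case_mean[i], pspec$case_sd[i], n_cases, pspec$family[i])
    v[group == "control"] <- draw(pspec$control_mean[i], pspec$control_sd[i], n_controls, pspec$family[i])
    conc[[pspec$name[i]]] <- v
  }
  # validation-cohort demographics: milder age gap than discovery
  age <- pmax(18, round(ifelse(group == "case", stats::rnorm(n, 61, 11.39),
                               stats::rnorm(n, 34, 12.54))))
  sex <- ifelse(stats::runif(n) < ifelse(group == "case", 24 / 47, 17 / 47), "male", "female")
  stage <- rep(NA_character_, n)
  stage[group == "case"] <- sample(c("I", "II", "III", "IV"), n_cases, replace = TRUE,
                                   prob = c(11, 9, 17, 10) / 47)
  site <- rep(NA_character_, n)
  site[group == "case"] <- sample(c("colon", "rectal"), n_cases, replace = TRUE,
                                  prob = c(12, 18) / 30)
  meta <- data.frame(sample_id = sample_id, group = group, cohort = cohort,
                     age = age, sex = sex, stage = stage, site = site,
                     stringsAsFactors = FALSE)
  units <- stats::setNames(pspec$unit, pspec$name)
  list(concentrations = conc, meta = meta, units = units)
}

#' Write cohort artifacts to disk
#'
#' Serializes a generated cohort in the same dialects the ingestion functions
#' read: wide peak table (CSV/TSV), metadata CSV, and ground truth JSON.
#'
#' @param cohort result of [generate_untargeted_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"tsv"` for the peak table.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    peak_table = file.path(dir, paste0("peak_table.", format)),
    meta = file.path(dir, "sample_meta.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_peak_table(cohort$matrix, paths[["peak_table"]])
  utils::write.csv(cohort$meta, paths[["meta"]], row.names = FALSE, quote = FALSE, na = "NA")
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
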