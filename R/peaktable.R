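# Aligned peak-table container and the post-alignment processing chain:
# minimum-height filter, internal-standard normalization, QC CV filter,
# missing-value imputation.

#' Construct a feature matrix
#'
#' The central container for aligned untargeted LC-MS data: a samples x
#' features intensity matrix plus per-feature m/z and retention time.
#' Missing intensities are `NA`; present intensities must be nonnegative.
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids.
#' @param features data.frame with columns `feature_id`, `mz` (Da), `rt`
#'   (minutes) and optionally `is_standard` (logical flag for spiked internal
#'   standards, default `FALSE`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(intensities, features) {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  stopifnot(is.data.frame(features))
  req <- c("feature_id", "mz", "rt")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("features table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"is_standard" %in% names(features)) features$is_standard <- FALSE
  features$feature_id <- as.character(features$feature_id)
  if (is.null(colnames(intensities))) colnames(intensities) <- features$feature_id
  if (is.null(rownames(intensities))) rownames(intensities) <- paste0("S", seq_len(nrow(intensities)))
  fm <- structure(list(intensities = intensities, features = features),
                  class = "feature_matrix")
  validate_feature_matrix(fm)
  fm
}

validate_feature_matrix <- function(fm) {
  x <- fm$intensities
  ft <- fm$features
  if (ncol(x) != nrow(ft)) stop("intensity columns (", ncol(x), ") != feature rows (", nrow(ft), ")", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate sample_ids", call. = FALSE)
  if (anyDuplicated(ft$feature_id)) stop("duplicate feature_ids", call. = FALSE)
  if (ncol(x) > 0 && !identical(colnames(x), ft$feature_id)) {
    stop("intensity column names do not match feature_ids", call. = FALSE)
  }
  if (any(ft$mz <= 0, na.rm = TRUE)) stop("mz must be > 0", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("present intensities must be >= 0", call. = FALSE)
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$intensities), " samples x ", ncol(x$intensities),
      " features (", sum(x$features$is_standard), " internal standards, ",
      sum(is.na(x$intensities)), " missing cells)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensities)

#' Subset a feature matrix by features (and optionally samples)
#'
#' @param fm a [feature_matrix()].
#' @param feature_ids character vector of feature ids to keep (order preserved
#'   as in `fm`).
#' @param sample_ids optional character vector of sample ids to keep.
#' @return A `feature_matrix`.
#' @export
subset_features <- function(fm, feature_ids, sample_ids = NULL) {
  keep <- fm$features$feature_id %in% feature_ids
  x <- fm$intensities[, keep, drop = FALSE]
  if (!is.null(sample_ids)) x <- x[rownames(x) %in% sample_ids, , drop = FALSE]
  feature_matrix(x, fm$features[keep, , drop = FALSE])
}

#' Read an aligned peak table
#'
#' Parses the wide alignment-export dialect: one row per spectral feature with
#' columns `feature_id`, `mz`, `rt`, then one intensity column per sample.
#' Empty cells and `"NA"` map to the internal missing marker (never zero).
#'
#' @param path file path; `.tsv`/`.txt` are tab-separated, otherwise comma.
#' @param sep field separator; overrides the extension heuristic.
#' @return A [feature_matrix()].
#' @export
read_peak_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  req <- c("feature_id", "mz", "rt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("peak table '", path, "' lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  samp_cols <- setdiff(names(df), c(req, "is_standard"))
  if (!length(samp_cols)) stop("peak table has no sample columns", call. = FALSE)
  for (cc in samp_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop("non-numeric intensity at row ", bad[1], ", column '", cc, "'", call. = FALSE)
      }
      df[[cc]] <- as.numeric(v)
    }
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id at row ", anyDuplicated(df$feature_id), call. = FALSE)
  }
  x <- t(as.matrix(df[, samp_cols, drop = FALSE]))
  colnames(x) <- df$feature_id
  rownames(x) <- samp_cols
  ft <- df[, intersect(c(req, "is_standard"), names(df)), drop = FALSE]
  feature_matrix(x, ft)
}

#' Write an aligned peak table
#'
#' Inverse of [read_peak_table()]; `read(write(fm))` round-trips values to
#' text float precision and preserves the missingness pattern exactly.
#'
#' @param fm a [feature_matrix()].
#' @param path output path; extension picks the separator as in
#'   [read_peak_table()].
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(fm, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- cbind(fm$features[, c("feature_id", "mz", "rt", "is_standard")],
               as.data.frame(t(fm$intensities), check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Minimum peak-height filter
#'
#' Retains features whose maximum present intensity reaches `threshold`
#' (inclusive). The default 30000 is the conventional minimum height cutoff
#' for high-resolution untargeted profiling at this instrument scale.
#'
#' @param fm a [feature_matrix()].
#' @param threshold nonnegative intensity threshold.
#' @return Filtered `feature_matrix`; sample set unchanged.
#' @export
filter_min_height <- function(fm, threshold = 30000) {
  stopifnot(threshold >= 0)
  mx <- apply(fm$intensities, 2, function(v) if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  keep <- fm$features$feature_id[mx >= threshold]
  subset_features(fm, keep)
}

#' Define the spiked internal-standard set
#'
#' Three isotope-labeled standards spiked at known levels are the anchors for
#' cross-sample intensity normalization: l-phenylalanine-3,3-d2 (30 nmol/mL),
#' cholic-2,2,4,4-d4 acid (2 nmol/mL) and lysophosphatidylcholine 19:0
#' (2 nmol/mL).
#'
#' @param feature_ids character vector of length 3: the matched feature ids in
#'   the peak table, in the order phenylalanine-d2, cholic-d4, lysoPC 19:0.
#' @param names,mz,spike_level optional overrides of the default compound
#'   names, expected monoisotopic masses (Da) and spike levels (nmol/mL).
#' @return data.frame of class `internal_standard_set`.
#' @export
internal_standard_set <- function(feature_ids,
                                  names = c("l-phenylalanine-3,3-d2",
                                            "cholic-2,2,4,4-d4 acid",
                                            "lysoPC 19:0"),
                                  mz = c(167.0915, 412.3127, 537.3794),
                                  spike_level = c(30, 2, 2)) {
  stopifnot(length(feature_ids) == length(names), length(names) == length(mz))
  structure(data.frame(name = names, mz = mz, spike_level = spike_level,
                       feature_id = as.character(feature_ids),
                       stringsAsFactors = FALSE),
            class = c("internal_standard_set", "data.frame"))
}

#' Internal-standard intensity normalization
#'
#' Divides each sample's intensities by that sample's geometric mean of the
#' internal-standard intensities (the composite of all three standards by
#' default), then rescales by the across-sample geometric mean of those
#' per-sample factors so the global intensity scale is preserved. The
#' operation is idempotent and invariant to per-sample multiplicative drift.
#'
#' `method = "per-is"` instead pairs every feature with the single standard
#' closest in retention time and normalizes by that standard alone.
#'
#' @param fm a [feature_matrix()].
#' @param is_set an [internal_standard_set()]; all its features must be
#'   present with no missing and strictly positive intensities.
#' @param method `"composite"` (default) or `"per-is"`.
#' @param reference optional fixed reference scale (composite mode: one
#'   number; per-is mode: one per standard). Supplying the reference makes
#'   the operation exactly invariant to rescaling any single sample;
#'   otherwise the reference is the across-sample geometric mean of the
#'   per-sample factors, which preserves the global scale of the data at
#'   hand.
#' @return A `feature_matrix` with internal-standard features flagged
#'   (`is_standard = TRUE`) so downstream selection can exclude them.
#' @export
normalize_internal_standards <- function(fm, is_set, method = c("composite", "per-is"),
                                         reference = NULL) {
  method <- match.arg(method)
  ids <- is_set$feature_id
  missing_is <- setdiff(ids, fm$features$feature_id)
  if (length(missing_is)) stop("internal standard feature(s) absent: ", paste(missing_is, collapse = ", "), call. = FALSE)
  x <- fm$intensities
  isx <- x[, ids, drop = FALSE]
  bad <- which(apply(isx, 1, function(v) any(is.na(v) | v <= 0)))
  if (length(bad)) {
    stop("internal standard missing or nonpositive in sample(s): ",
         paste(rownames(x)[bad], collapse = ", "), call. = FALSE)
  }
  ft <- fm$features
  ft$is_standard <- ft$is_standard | ft$feature_id %in% ids
  if (method == "composite") {
    f <- apply(isx, 1, geometric_mean)        # per-sample composite IS level
    ref <- reference %||% geometric_mean(f)   # across-sample reference scale
    y <- x * (ref / f)                        # rows scaled; global scale kept
  } else {
    rt_is <- ft$rt[match(ids, ft$feature_id)]
    pair <- ids[apply(abs(outer(ft$rt, rt_is, "-")), 1, which.min)]
    ref <- reference %||% apply(isx, 2, geometric_mean)
    names(ref) <- ids
    y <- x
    for (j in seq_len(ncol(x))) {
      is_j <- pair[j]
      y[, j] <- x[, j] * (ref[is_j] / x[, is_j])
    }
  }
  feature_matrix(y, ft)
}

#' QC coefficient-of-variation filter
#'
#' Retains features whose coefficient of variation (sd/mean) across pooled-QC
#' replicate injections is strictly below `cv_max` (default 15%, the
#' conventional analytical-reproducibility bound). Features with a QC mean of
#' zero are removed and reported via a warning.
#'
#' @param fm a [feature_matrix()] of study samples.
#' @param qc_fm a `feature_matrix` of >= 2 QC replicate injections covering
#'   the same features.
#' @param cv_max maximum acceptable CV (fraction).
#' @return Filtered `feature_matrix`.
#' @export
filter_qc_cv <- function(fm, qc_fm, cv_max = 0.15) {
  if (nrow(qc_fm$intensities) < 2) stop("need >= 2 QC replicates", call. = FALSE)
  common <- intersect(fm$features$feature_id, qc_fm$features$feature_id)
  q <- qc_fm$intensities[, common, drop = FALSE]
  mu <- colMeans(q, na.rm = TRUE)
  sdv <- apply(q, 2, stats::sd, na.rm = TRUE)
  zero_mean <- !is.na(mu) & mu == 0
  if (any(zero_mean)) {
    warning(sum(zero_mean), " feature(s) removed: QC mean 0")
  }
  cv <- sdv / mu
  keep <- common[which(!zero_mean & !is.na(cv) & cv < cv_max)]
  # features absent from the QC table cannot be assessed and are dropped
  subset_features(fm, keep)
}

#' Impute missing intensities
#'
#' `"half-min"` (default) replaces each feature's missing cells with half that
#' feature's minimum present intensity, the standard left-censoring surrogate
#' for below-detection-limit peaks; `"zero"` substitutes 0.
#'
#' @param fm a [feature_matrix()]; every feature must have at least one
#'   present value (filter all-missing features first).
#' @param strategy `"half-min"` or `"zero"`.
#' @return A `feature_matrix` without missing values.
#' @export
impute_missing <- function(fm, strategy = c("half-min", "zero")) {
  strategy <- match.arg(strategy)
  x <- fm$intensities
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    stop("feature(s) with no present values: ",
         paste(utils::head(colnames(x)[all_na], 5), collapse = ", "),
         " - filter them before imputation", call. = FALSE)
  }
  for (j in which(colSums(is.na(x)) > 0)) {
    fill <- if (strategy == "half-min") min(x[, j], na.rm = TRUE) / 2 else 0
    x[is.na(x[, j]), j] <- fill
  }
  feature_matrix(x, fm$features)
}
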