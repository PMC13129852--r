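# Per-feature univariate statistics: volcano (fold change + rank test + BH),
# rank-based ROC AUC with the direction-agnostic triage rule, and simplified
# MS1/MS2 annotation matching.

#' Volcano statistics for every feature
#'
#' Per feature: log2 fold change of arithmetic group means (case over
#' control), two-sided Mann-Whitney p-value, Benjamini-Hochberg q-value, and
#' a class label: `up` / `down` when `q < q_threshold` and
#' `|log2FC| >= fc_threshold_log2`, otherwise `ns`. Features whose control
#' mean is zero have an undefined fold change and are flagged
#' (`class = "undefined"`, excluded from up/down classing).
#'
#' @param x samples x features numeric matrix (normalized intensities),
#'   missing allowed (ignored per group mean/test).
#' @param labels two-class labels; first level (or `case`) is the case group.
#' @param q_threshold BH q cutoff (default 0.05).
#' @param fc_threshold_log2 absolute log2 fold-change cutoff (default
#'   `log2(1.5)`).
#' @param case optional case-level name.
#' @return data.frame `feature_id, log2fc, p, q, class`.
#' @export
volcano <- function(x, labels, q_threshold = 0.05, fc_threshold_log2 = log2(1.5),
                    case = NULL) {
  y <- as_case_control(labels, case)
  if (min(table(y)) < 3) stop("both classes need n >= 3", call. = FALSE)
  ic <- y == levels(y)[1]
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  m_case <- colMeans(x[ic, , drop = FALSE], na.rm = TRUE)
  m_ctrl <- colMeans(x[!ic, , drop = FALSE], na.rm = TRUE)
  l2fc <- suppressWarnings(log2(m_case / m_ctrl))
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[ic, j]; b <- x[!ic, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  cls <- rep("ns", ncol(x))
  undef <- !is.finite(l2fc) | m_ctrl == 0
  sig <- !undef & !is.na(q) & q < q_threshold & abs(l2fc) >= fc_threshold_log2
  cls[sig & l2fc > 0] <- "up"
  cls[sig & l2fc < 0] <- "down"
  cls[undef] <- "undefined"
  data.frame(feature_id = colnames(x), log2fc = l2fc, p = p, q = q,
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-based ROC AUC of one feature
#'
#' AUC for case-vs-control discrimination by pair counting: the fraction of
#' case-control pairs in which the case value exceeds the control value, ties
#' counted one half — the Mann-Whitney U statistic normalized by
#' `n_case * n_control`. Computed via midranks, which is exactly equivalent.
#'
#' @param values numeric vector (missing dropped with its label).
#' @param labels two-class labels aligned with `values`.
#' @param case optional case-level name (default: first factor level).
#' @return list of class `auc_record`: `auc` in \[0, 1\], `direction`
#'   (`"higher-in-case"` or `"lower-in-case"`), `n_case`, `n_control`.
#' @export
feature_auc <- function(values, labels, case = NULL) {
  y <- as_case_control(labels, case)
  keep <- !is.na(values)
  values <- values[keep]; y <- droplevels(y[keep])
  if (nlevels(y) < 2) stop("both classes must be nonempty", call. = FALSE)
  ic <- y == levels(y)[1]
  n1 <- sum(ic); n2 <- sum(!ic)
  r <- rank(values) # midranks handle ties as half-pairs
  auc <- (sum(r[ic]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  structure(list(auc = auc,
                 direction = if (auc >= 0.5) "higher-in-case" else "lower-in-case",
                 n_case = n1, n_control = n2),
            class = "auc_record")
}

#' Direction-agnostic AUC triage
#'
#' Retains features whose discriminative AUC exceeds `threshold` strictly, in
#' either direction: a feature is kept when `max(AUC, 1 - AUC) > threshold`.
#' Direction-agnosticism matters because discriminatory metabolites are often
#' reduced, not elevated, in disease.
#'
#' @param auc named numeric vector of per-feature AUCs (or a list of
#'   `auc_record`s with names).
#' @param threshold strict lower bound (default 0.90).
#' @return Character vector of retained feature names (empty input gives an
#'   empty output).
#' @export
auc_filter <- function(auc, threshold = 0.90) {
  if (is.list(auc)) auc <- vapply(auc, function(r) r$auc, numeric(1))
  if (!length(auc)) return(character(0))
  names(auc)[pmax(auc, 1 - auc) > threshold]
}

# "mz:intensity;mz:intensity" -> two-column matrix
parse_ms2_peaks <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity"))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("mz", "intensity")
  m
}

#' Cosine similarity of two MS2 peak lists
#'
#' Peaks are paired greedily by closest m/z within `tol`; the score is the
#' cosine of the intensity vectors over the union of peaks (unmatched peaks
#' contribute only to the norms). Identical spectra score 1, disjoint peak
#' sets score 0.
#'
#' @param a,b two-column matrices `(mz, intensity)` as from
#'   `parse_ms2_peaks`.
#' @param tol m/z pairing tolerance in Da (default 0.025).
#' @return Cosine score in \[0, 1\], or `NA` when either spectrum is empty
#'   (a zero-length intensity vector has no direction to compare).
#' @export
ms2_cosine <- function(a, b, tol = 0.025) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  # greedy pairing: smallest |dmz| first, each peak used once
  d <- abs(outer(a[, "mz"], b[, "mz"], "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  num <- 0
  if (nrow(cand) > 0) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_a[i] && !used_b[j]) {
        num <- num + a[i, "intensity"] * b[j, "intensity"]
        used_a[i] <- TRUE; used_b[j] <- TRUE
      }
    }
  }
  unname(num / (sqrt(sum(a[, "intensity"]^2)) * sqrt(sum(b[, "intensity"]^2))))
}

#' Read an annotation reference table
#'
#' CSV with columns `compound`, `monoisotopic_mass` (Da) and `ms2_peaks`
#' (semicolon-separated `mz:intensity` pairs).
#'
#' @param path file path.
#' @return data.frame with a `peaks` list-column of parsed peak matrices.
#' @export
read_annotation_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("compound", "monoisotopic_mass", "ms2_peaks")
  miss <- setdiff(req, names(ref))
  if (length(miss)) stop("annotation reference lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ref$peaks <- lapply(ref$ms2_peaks, parse_ms2_peaks)
  ref
}

#' Annotate features against a reference library
#'
#' For each feature, candidate compounds are references whose monoisotopic
#' mass lies within `ms1_tol` of the feature m/z; the MS2 score is the cosine
#' similarity of the fragmentation patterns with peak pairing within
#' `ms2_tol`. The best-scoring candidate is reported; a match is `accepted`
#' iff its score reaches `score_min`. When neither side carries MS2 peaks the
#' score is undefined and the MS1-only match is reported with
#' `accepted = FALSE`.
#'
#' @param features data.frame with `feature_id`, `mz`, and optionally
#'   `ms2_peaks` (same text dialect as the reference).
#' @param reference data.frame from [read_annotation_reference()].
#' @param ms1_tol MS1 mass tolerance in Da (default 0.01).
#' @param ms2_tol MS2 pairing tolerance in Da (default 0.025).
#' @param score_min minimum identification score (default 0.80).
#' @return data.frame `feature_id, compound, ms1_error, ms2_score, accepted`
#'   with one row per feature that has at least one MS1 candidate.
#' @export
annotate_features <- function(features, reference, ms1_tol = 0.01,
                              ms2_tol = 0.025, score_min = 0.80) {
  stopifnot(all(c("feature_id", "mz") %in% names(features)))
  if (is.null(reference$peaks)) reference$peaks <- lapply(reference$ms2_peaks, parse_ms2_peaks)
  fpeaks <- if ("ms2_peaks" %in% names(features)) {
    lapply(features$ms2_peaks, parse_ms2_peaks)
  } else {
    rep(list(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))),
        nrow(features))
  }
  rows <- list()
  for (i in seq_len(nrow(features))) {
    err <- reference$monoisotopic_mass - features$mz[i]
    cand <- which(abs(err) <= ms1_tol)
    if (!length(cand)) next
    score <- vapply(cand, function(j) ms2_cosine(fpeaks[[i]], reference$peaks[[j]], ms2_tol),
                    numeric(1))
    best <- if (all(is.na(score))) cand[which.min(abs(err[cand]))] else cand[which.max(score)]
    bscore <- score[match(best, cand)]
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = features$feature_id[i],
      compound = reference$compound[best],
      ms1_error = -err[best],
      ms2_score = bscore,
      accepted = !is.na(bscore) && bscore >= score_min,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(feature_id = character(0), compound = character(0),
                      ms1_error = numeric(0), ms2_score = numeric(0),
                      accepted = logical(0)))
  }
  do.call(rbind, rows)
}
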