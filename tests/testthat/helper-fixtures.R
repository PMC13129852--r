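# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (double loops, exhaustive scans) so they cannot share a
# code path with the implementation they check.

tiny_feature_matrix <- function(values = NULL, n_samples = 2, n_features = 3) {
  if (is.null(values)) {
    values <- matrix(seq_len(n_samples * n_features) * 1000, n_samples, n_features)
  }
  rownames(values) <- paste0("S", seq_len(nrow(values)))
  feats <- data.frame(feature_id = paste0("F", seq_len(ncol(values))),
                      mz = 100 + seq_len(ncol(values)),
                      rt = seq_len(ncol(values)))
  colnames(values) <- feats$feature_id
  feature_matrix(values, feats)
}

# brute-force AUC: count all case-control pairs, ties half
auc_pair_oracle <- function(values, labels, case) {
  cs <- values[labels == case]
  ct <- values[labels != case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# exhaustive Youden scan over every candidate midpoint, both directions
youden_oracle <- function(values, labels, case, direction) {
  u <- sort(unique(values))
  cand <- if (length(u) < 2) u else (u[-1] + u[-length(u)]) / 2
  ic <- labels == case
  best_j <- -Inf
  for (cut in cand) {
    pos <- if (direction == "below") values < cut else values > cut
    j <- mean(pos[ic]) + mean(!pos[!ic]) - 1
    if (j > best_j) best_j <- j
  }
  best_j
}

small_cohort <- function(seed = 1, ...) {
  generate_untargeted_cohort(cohort_spec(
    n_cases = 30, n_controls = 25, n_features = 120,
    n_markers_down = 6, n_markers_up = 3, missing_rate = 0.03, seed = seed, ...))
}
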