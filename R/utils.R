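# Internal helpers shared across modules.

# A type-stable percentile threshold: value v is selected by an upper
# percentile p when v >= quantile(scores, p/100) (ties kept at the boundary).
upper_percentile_cut <- function(scores, pct) {
  stopifnot(is.numeric(scores), length(scores) > 0, pct >= 0, pct <= 100)
  unname(quantile(scores, probs = pct / 100, type = 7, names = FALSE))
}

# Derive a child seed from a user seed so that independent stages draw from
# independent streams while remaining reproducible. Kept below 2^31.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(tag) %% 997L
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Trapezoidal ROC AUC via the rank (Mann-Whitney) statistic; tie-robust.
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("AUC needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
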