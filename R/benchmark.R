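# Manual-gating baselines and ROC / precision-recall evaluation used to
# benchmark the image-based and cluster-based classifiers.

#' Apply quadrant and polygon gates to a preprocessed cohort
#'
#' Quadrant gates split cells by per-channel positivity (above the
#' autofluorescence threshold, i.e. `blue_norm > 0` / `red_norm > 0`).
#' Polygon-Blue(high) keeps Blue-positive cells above the Blue-Red
#' diagonal (`blue_norm > red_norm`); Polygon-Red(high) keeps Blue-positive
#' cells on or below it (`red_norm >= blue_norm`; diagonal ties go to
#' Red(high)). Per-sample gate percentages (of all cells), %Timer+ and the
#' mean Timer Angle form the gate feature table.
#'
#' @param cells Preprocessed cell table with `sample_id`, `blue_norm`,
#'   `red_norm`, `timer_positive`, `angle_deg` (and optionally `group`).
#' @return Tibble, one row per sample: `pct_blue_pos_red_neg`,
#'   `pct_blue_pos_red_pos`, `pct_blue_neg_red_pos`, `pct_double_neg`,
#'   `pct_polygon_blue_high`, `pct_polygon_red_high`, `pct_timer_pos`,
#'   `mean_angle`.
#' @export
apply_gates <- function(cells) {
  assert_columns(cells, c("sample_id", "blue_norm", "red_norm",
                          "timer_positive", "angle_deg"), "cell table")
  keys <- intersect(c("sample_id", "group", "cohort"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      pct_blue_pos_red_neg = 100 * mean(.data$blue_norm > 0 & .data$red_norm == 0),
      pct_blue_pos_red_pos = 100 * mean(.data$blue_norm > 0 & .data$red_norm > 0),
      pct_blue_neg_red_pos = 100 * mean(.data$blue_norm == 0 & .data$red_norm > 0),
      pct_double_neg = 100 * mean(!.data$timer_positive),
      pct_polygon_blue_high = 100 * mean(.data$blue_norm > 0 &
                                           .data$blue_norm > .data$red_norm),
      pct_polygon_red_high = 100 * mean(.data$blue_norm > 0 &
                                          .data$red_norm >= .data$blue_norm),
      pct_timer_pos = 100 * mean(.data$timer_positive),
      mean_angle = if (any(.data$timer_positive))
        mean(.data$angle_deg[.data$timer_positive]) else NA_real_,
      .groups = "drop"
    )
}

#' Per-sample mean Timer Angle
#'
#' @param cells Preprocessed cell table.
#' @return Tibble `sample_id` (+ `group`), `mean_angle` (degrees over
#'   Timer+ cells; `NA` with a flag when a sample has none).
#' @export
mean_timer_angle <- function(cells) {
  assert_columns(cells, c("sample_id", "angle_deg", "timer_positive"), "cell table")
  keys <- intersect(c("sample_id", "group", "cohort"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_angle = if (any(.data$timer_positive))
        mean(.data$angle_deg[.data$timer_positive]) else NA_real_,
      flag_no_timer = !any(.data$timer_positive),
      .groups = "drop")
}

#' Logistic-regression classifier on gate features
#'
#' Maximum-likelihood logistic regression (binomial `glm`, no
#' regularisation) of group on manual-gating features; predicted
#' probabilities on the test table are thresholded at 0.5 for labels and
#' evaluated by ROC and precision-recall.
#'
#' @param train,test Gate feature tables from [apply_gates()] with a
#'   `group` column (2 groups).
#' @param features Feature columns to use; defaults to every `pct_*` and
#'   `mean_angle` column.
#' @return List: `fit` (the glm), `predictions` (test tibble with `.prob`,
#'   `.pred_class`), `accuracy`, and `metrics` from [evaluate_roc_pr()].
#' @export
logistic_gate_classifier <- function(train, test,
                                     features = NULL) {
  assert_columns(train, "group", "gate feature table")
  if (is.null(features)) {
    features <- c(grep("^pct_", names(train), value = TRUE),
                  intersect("mean_angle", names(train)))
  }
  lv <- sort(unique(as.character(train$group)))
  if (length(lv) != 2) abort("logistic gate classifier needs exactly 2 groups")
  df_tr <- as.data.frame(train[, features])
  df_tr$.y <- as.integer(as.character(train$group) == lv[2])
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df_tr, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warn("perfect separation in gate features; unregularised fit retained")
        invokeRestart("muffleWarning")
      }
    })
  prob <- suppressWarnings(
    predict(fit, newdata = as.data.frame(test[, features]), type = "response"))
  pred <- tibble::as_tibble(test[, intersect(c("sample_id", "group"), names(test))])
  pred$.prob <- as.numeric(prob)
  pred$.pred_class <- ifelse(pred$.prob > 0.5, lv[2], lv[1])
  metrics <- evaluate_roc_pr(pred$.prob, test$group == lv[2])
  list(fit = fit, positive_class = lv[2], predictions = pred,
       accuracy = mean(pred$.pred_class == as.character(test$group)),
       metrics = metrics)
}

#' ROC and precision-recall evaluation
#'
#' Trapezoidal ROC AUC (tie-robust rank form) and average precision
#' (precision-weighted recall increments over score thresholds). For
#' multiclass labels, one-vs-rest curves are computed per class from a
#' score matrix and macro-averaged.
#'
#' @param scores Numeric vector (binary) or matrix/data frame with one
#'   column per class (multiclass).
#' @param labels Logical/0-1 vector (binary) or class labels (multiclass).
#' @return List with `auc`, `average_precision`, `roc` (tibble `fpr`,
#'   `tpr`), `pr` (tibble `recall`, `precision`); for multiclass,
#'   `per_class` plus macro-averaged `auc` and `average_precision`.
#' @export
evaluate_roc_pr <- function(scores, labels) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.data.frame(scores)
    classes <- colnames(scores)
    per <- purrr::map(setNames(classes, classes), function(cl) {
      evaluate_roc_pr(scores[[cl]], as.character(labels) == cl)
    })
    return(list(
      auc = mean(vapply(per, `[[`, 1, "auc")),
      average_precision = mean(vapply(per, `[[`, 1, "average_precision")),
      per_class = per
    ))
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("need at least one positive and one negative label")
  }
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  n1 <- sum(y)
  n0 <- sum(!y)
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)     # threshold boundaries (ties pooled)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  prec <- (tp / (tp + fp))[last]
  rec <- tpr[-1]
  ap <- sum(diff(c(0, rec)) * prec)
  list(
    auc = rank_auc(scores, labels),
    average_precision = ap,
    roc = tibble::tibble(fpr = fpr, tpr = tpr),
    pr = tibble::tibble(recall = c(0, rec), precision = c(1, prec))
  )
}
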