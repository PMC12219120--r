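# broom-style tidiers for the fitted objects.

#' @exportS3Method generics::tidy
tidy.tocky_rf <- function(x, ...) {
  tibble::tibble(
    term = x$features,
    mdg = unname(x$mdg)
  ) |> dplyr::arrange(dplyr::desc(.data$mdg))
}

#' @exportS3Method generics::glance
glance.tocky_rf <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    n_features = length(x$features),
    n_classes = length(x$levels),
    oob_error = x$oob_error
  )
}

#' @exportS3Method generics::tidy
tidy.tocky_kmeans <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = as.integer(table(factor(x$cells$cluster, levels = seq_len(x$k)))),
    median_angle_z = x$medians[, "angle"],
    median_intensity_z = x$medians[, "intensity"]
  )
}

#' @exportS3Method generics::glance
glance.tocky_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n_cells = nrow(x$cells),
                 n_samples = length(unique(x$cells$sample_id)))
}

#' @exportS3Method generics::tidy
tidy.cluster_match <- function(x, ...) {
  k <- length(x$assignment)
  tibble::tibble(
    train_cluster = seq_len(k),
    test_cluster = x$assignment,
    distance = x$D[cbind(seq_len(k), x$assignment)]
  )
}

#' @exportS3Method generics::glance
glance.cluster_match <- function(x, ...) {
  tibble::tibble(k = length(x$assignment), cost = x$cost)
}

#' @exportS3Method generics::tidy
tidy.tocky_convnet_cv <- function(x, ...) {
  x$fold_history
}

#' @exportS3Method generics::glance
glance.tocky_convnet_cv <- function(x, ...) {
  tibble::tibble(folds = length(x$fold_accuracy),
                 cv_accuracy = x$cv_accuracy)
}

#' @exportS3Method generics::tidy
tidy.timer_score_fit <- function(x, ...) {
  x$table
}

#' @exportS3Method generics::glance
glance.timer_score_fit <- function(x, ...) {
  dplyr::summarise(x$table,
                   organs = dplyr::n(),
                   mean_r_squared_log = mean(.data$r_squared_log),
                   mean_r_squared_raw = mean(.data$r_squared_raw))
}
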