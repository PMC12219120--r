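# ggplot2 displays. Rows of a timer_image index intensity bins, so display
# flips nothing: ggplot's y axis already increases upward.

#' @exportS3Method ggplot2::autoplot
autoplot.timer_image <- function(object, ...) {
  g <- object$grid
  df <- expand.grid(
    intensity = (g$intensity_edges[-1] + g$intensity_edges[-(g$n_bins + 1)]) / 2,
    angle = (g$angle_edges[-1] + g$angle_edges[-(g$n_bins + 1)]) / 2
  )
  df$density <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(.data$angle, .data$intensity,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "Timer Angle (deg)", y = "Timer Intensity",
                  fill = if (object$normalized) "density" else "count",
                  title = object$sample_id) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cam_map <- function(object, ...) {
  n <- nrow(object$map)
  df <- expand.grid(row = seq_len(n), col = seq_len(n))
  df$value <- as.vector(object$map)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "angle bin", y = "intensity bin", fill = "CAM",
                  title = sprintf("%s / class %s", object$layer, object$class)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cam_differential <- function(object, ...) {
  n <- nrow(object$map)
  df <- expand.grid(row = seq_len(n), col = seq_len(n))
  df$value <- as.vector(object$map)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "angle bin", y = "intensity bin",
                  fill = sprintf("%s - %s", object$minuend, object$subtrahend)) +
    ggplot2::theme_minimal()
}

#' Scatter display of Timer Angle vs Intensity
#'
#' @param cells Preprocessed cell table.
#' @param colour Optional column name to colour by (e.g. `"locus"`,
#'   `"cluster"`, `"cam_score"`).
#' @return A ggplot.
#' @export
plot_timer_scatter <- function(cells, colour = "locus") {
  pos <- cells[cells$timer_positive, , drop = FALSE]
  p <- ggplot2::ggplot(pos, ggplot2::aes(.data$angle_deg, .data$intensity))
  if (!is.null(colour) && colour %in% names(pos)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 0.3, alpha = 0.5)
  } else {
    p <- p + ggplot2::geom_point(size = 0.3, alpha = 0.5)
  }
  p + ggplot2::labs(x = "Timer Angle (deg)", y = "Timer Intensity") +
    ggplot2::theme_minimal()
}

#' Training curves of a cross-validated ConvNet
#'
#' @param cv A [convnet_crossval()] result.
#' @return A ggplot of per-fold validation accuracy by epoch.
#' @export
plot_cv_history <- function(cv) {
  stopifnot(inherits(cv, "tocky_convnet_cv"))
  df <- tidyr::pivot_longer(cv$fold_history,
                            c("accuracy", "val_accuracy"),
                            names_to = "split", values_to = "acc")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$acc,
                                   colour = factor(.data$fold),
                                   linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "accuracy", colour = "fold") +
    ggplot2::theme_minimal()
}

#' ROC curve display
#'
#' @param metrics Result of [evaluate_roc_pr()] (binary).
#' @return A ggplot.
#' @export
plot_roc <- function(metrics) {
  stopifnot(!is.null(metrics$roc))
  ggplot2::ggplot(metrics$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", metrics$auc)) +
    ggplot2::theme_minimal()
}
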