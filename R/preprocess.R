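#' Estimate autofluorescence thresholds from a negative control
#'
#' Per-channel thresholds are the given quantile of log10 raw fluorescence
#' of a Timer-negative control population; cells below threshold in a
#' channel are treated as autofluorescent in that channel.
#'
#' @param negative Data frame of control cells with `blue_raw`, `red_raw`
#'   (> 0); at least 100 cells.
#' @param quantile Quantile in (0.5, 1]; default 0.999.
#' @return A `timer_thresholds` object: `threshold_blue`, `threshold_red`
#'   (log10 a.u.) and the quantile used.
#' @export
#' @examples
#' neg <- data.frame(blue_raw = rlnorm(500, 4), red_raw = rlnorm(500, 4))
#' estimate_thresholds(neg)
estimate_thresholds <- function(negative, quantile = 0.999) {
  assert_columns(negative, c("blue_raw", "red_raw"), "negative control")
  if (nrow(negative) < 100) {
    abort(sprintf("negative control needs >= 100 cells; got %d", nrow(negative)))
  }
  if (!(quantile > 0.5 && quantile <= 1)) abort("quantile must be in (0.5, 1]")
  if (any(negative$blue_raw <= 0) || any(negative$red_raw <= 0)) {
    abort("raw fluorescence must be > 0")
  }
  structure(
    list(
      threshold_blue = unname(stats::quantile(log10(negative$blue_raw), quantile)),
      threshold_red = unname(stats::quantile(log10(negative$red_raw), quantile)),
      quantile = quantile
    ),
    class = "timer_thresholds"
  )
}

#' @export
print.timer_thresholds <- function(x, ...) {
  cat(sprintf("Timer thresholds (log10 a.u., q = %.4g): blue %.4g, red %.4g\n",
              x$quantile, x$threshold_blue, x$threshold_red))
  if (!is.null(x$scale_blue)) {
    cat(sprintf("  channel scale factors: blue %.4g, red %.4g\n",
                x$scale_blue, x$scale_red))
  }
  invisible(x)
}

#' Normalize Timer channels against autofluorescence thresholds
#'
#' Each channel is thresholded on the log10 scale,
#' `v = max(0, log10(raw) - threshold)`, then rescaled by its own
#' cohort-wide 99.9th percentile positive value so both fluorescence types
#' span approximately `[0, 1]` and are treated equally. A cell is Timer
#' positive when it exceeds the threshold in either channel.
#'
#' @param cells Data frame with `blue_raw`, `red_raw` (> 0).
#' @param thresholds A `timer_thresholds` object (from
#'   [estimate_thresholds()] or built manually).
#' @param scale_quantile Quantile of positive values used as the per-channel
#'   scale factor (default 0.999).
#' @return Input tibble with `blue_norm`, `red_norm`, `timer_positive`
#'   added; the scale factors used are recorded on the returned
#'   `"thresholds"` attribute.
#' @export
normalize_channels <- function(cells, thresholds, scale_quantile = 0.999) {
  assert_columns(cells, c("blue_raw", "red_raw"), "cell table")
  stopifnot(inherits(thresholds, "timer_thresholds"))
  if (any(cells$blue_raw <= 0) || any(cells$red_raw <= 0)) {
    abort("raw fluorescence must be > 0")
  }
  out <- tibble::as_tibble(cells)
  norm1 <- function(raw, thr, chan) {
    v <- pmax(0, log10(raw) - thr)
    pos <- v[v > 0]
    if (length(pos) == 0) {
      warn(sprintf("no %s-positive cells in cohort; scale factor set to 1", chan))
      sc <- 1
    } else {
      sc <- unname(stats::quantile(pos, scale_quantile))
    }
    list(v = v / sc, scale = sc)
  }
  nb <- norm1(cells$blue_raw, thresholds$threshold_blue, "blue")
  nr <- norm1(cells$red_raw, thresholds$threshold_red, "red")
  out$blue_norm <- nb$v
  out$red_norm <- nr$v
  out$timer_positive <- out$blue_norm > 0 | out$red_norm > 0
  thresholds$scale_blue <- nb$scale
  thresholds$scale_red <- nr$scale
  thresholds$scale_quantile <- scale_quantile
  attr(out, "thresholds") <- thresholds
  out
}

#' Transform normalized Timer fluorescence to Angle and Intensity
#'
#' Timer Angle is measured in degrees from the Blue axis towards the Red
#' axis: a cell with only blue (immature) fluorescence has angle 0 (new
#' transcription) and a cell with only red (mature) fluorescence has angle
#' 90 (arrested). Timer Intensity is the Euclidean norm of the normalized
#' (blue, red) vector. Timer-negative cells get `NA` angle and intensity 0.
#'
#' @param cells Data frame with `blue_norm`, `red_norm`, `timer_positive`.
#' @return Input tibble with `angle_deg`, `intensity` added.
#' @export
#' @examples
#' df <- data.frame(blue_norm = c(0.5, 0, 0.3), red_norm = c(0, 0.5, 0.3),
#'                  timer_positive = TRUE)
#' transform_polar(df)$angle_deg
transform_polar <- function(cells) {
  assert_columns(cells, c("blue_norm", "red_norm", "timer_positive"), "cell table")
  out <- tibble::as_tibble(cells)
  angle <- atan2(out$red_norm, out$blue_norm) * 180 / pi
  intensity <- sqrt(out$blue_norm^2 + out$red_norm^2)
  angle[!out$timer_positive] <- NA_real_
  intensity[!out$timer_positive] <- 0
  out$angle_deg <- angle
  out$intensity <- intensity
  out
}

#' Classify cells into Timer loci
#'
#' Timer loci partition the angle axis: New (exactly 0), NPt (0-30],
#' Persistent (30-60], PAt (60-90), Arrested (exactly 90); Timer-negative
#' cells are Negative. Interior bands are left-open/right-closed.
#'
#' @param cells Data frame with `angle_deg`, `timer_positive`.
#' @return Input tibble with factor column `locus` added.
#' @export
classify_locus <- function(cells) {
  assert_columns(cells, c("angle_deg", "timer_positive"), "cell table")
  out <- tibble::as_tibble(cells)
  a <- out$angle_deg
  locus <- dplyr::case_when(
    !out$timer_positive ~ "Negative",
    a == 0 ~ "New",
    a > 0 & a <= 30 ~ "NPt",
    a > 30 & a <= 60 ~ "Persistent",
    a > 60 & a < 90 ~ "PAt",
    a == 90 ~ "Arrested"
  )
  out$locus <- factor(locus, levels = timer_locus_levels())
  out
}

#' @rdname classify_locus
#' @export
timer_locus_levels <- function() {
  c("New", "NPt", "Persistent", "PAt", "Arrested", "Negative")
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper: [normalize_channels()] then [transform_polar()] then
#' [classify_locus()].
#'
#' @inheritParams normalize_channels
#' @return Preprocessed tibble (see the component functions).
#' @export
preprocess_timer <- function(cells, thresholds, scale_quantile = 0.999) {
  cells |>
    normalize_channels(thresholds, scale_quantile) |>
    transform_polar() |>
    classify_locus()
}

#' Per-sample Timer locus composition
#'
#' @param cells Preprocessed table with `sample_id`, `locus`,
#'   `timer_positive` (and optionally `group`).
#' @return Tibble with one row per sample: `pct_timer_pos` (% of all cells)
#'   and one `pct_<locus>` column per locus as a percentage of Timer+
#'   cells. Samples without Timer+ cells have `NA` locus percentages and
#'   `flag_no_timer = TRUE`.
#' @export
locus_percentages <- function(cells) {
  assert_columns(cells, c("sample_id", "locus", "timer_positive"), "cell table")
  loci <- setdiff(timer_locus_levels(), "Negative")
  grp_cols <- intersect(c("sample_id", "group", "cohort"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::group_modify(function(df, key) {
      n_all <- nrow(df)
      n_pos <- sum(df$timer_positive)
      row <- tibble::tibble(
        n_cells = n_all,
        pct_timer_pos = 100 * n_pos / n_all,
        flag_no_timer = n_pos == 0
      )
      for (l in loci) {
        row[[paste0("pct_", l)]] <-
          if (n_pos == 0) NA_real_ else 100 * sum(df$locus == l) / n_pos
      }
      row
    }) |>
    dplyr::ungroup()
}
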