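#' Build a shared Angle-Intensity bin grid
#'
#' The grid spans the global minimum to maximum of Timer Angle and Timer
#' Intensity over the union of all supplied cohorts (training and test data
#' share one grid), divided into `n_bins` equidistant intervals per axis.
#'
#' @param ... One or more preprocessed cell tables (with `angle_deg`,
#'   `intensity`, `timer_positive`).
#' @param n_bins Bins per axis (default 100).
#' @return A `timer_grid` object with axis ranges, bin width and edges.
#' @export
#' @examples
#' df <- data.frame(angle_deg = c(0, 45, 90), intensity = c(0.2, 0.5, 1),
#'                  timer_positive = TRUE)
#' timer_grid(df, n_bins = 10)
timer_grid <- function(..., n_bins = 100) {
  tables <- list(...)
  stopifnot(length(tables) >= 1, n_bins >= 1)
  pos <- purrr::map_dfr(tables, function(t) {
    assert_columns(t, c("angle_deg", "intensity", "timer_positive"), "cell table")
    tibble::tibble(angle_deg = t$angle_deg, intensity = t$intensity)[t$timer_positive, ]
  })
  if (nrow(pos) == 0) abort("no Timer+ cells: cannot build a grid")
  rng_a <- range(pos$angle_deg)
  rng_i <- range(pos$intensity)
  if (rng_a[1] == rng_a[2] || rng_i[1] == rng_i[2]) {
    abort("degenerate axis: min equals max; need spread on both axes")
  }
  structure(
    list(
      angle_min = rng_a[1], angle_max = rng_a[2],
      intensity_min = rng_i[1], intensity_max = rng_i[2],
      n_bins = as.integer(n_bins),
      angle_edges = seq(rng_a[1], rng_a[2], length.out = n_bins + 1),
      intensity_edges = seq(rng_i[1], rng_i[2], length.out = n_bins + 1)
    ),
    class = "timer_grid"
  )
}

#' @export
print.timer_grid <- function(x, ...) {
  cat(sprintf("timer_grid: %d x %d bins, angle [%.3g, %.3g] deg, intensity [%.3g, %.3g]\n",
              x$n_bins, x$n_bins, x$angle_min, x$angle_max,
              x$intensity_min, x$intensity_max))
  invisible(x)
}

# 0-based bin index along one axis; bins are [e_i, e_{i+1}) with the final
# bin right-closed; out-of-range values clip to the edge bins.
axis_bin <- function(x, lo, hi, n) {
  i <- floor((x - lo) / (hi - lo) * n)
  pmin(pmax(i, 0), n - 1)
}

#' Map cells to pixel indices
#'
#' Deterministic cell-to-pixel mapping consistent with
#' [rasterize_sample()]: 0-based `(row, col)` with row = intensity bin and
#' col = angle bin; out-of-grid cells clip to edge bins and are flagged.
#' Timer-negative cells receive `NA` indices.
#'
#' @param cells Preprocessed cell table.
#' @param grid A [timer_grid()].
#' @return Input tibble with `pixel_row`, `pixel_col` (0-based) and
#'   `clipped` added.
#' @export
cell_pixel_index <- function(cells, grid) {
  stopifnot(inherits(grid, "timer_grid"))
  assert_columns(cells, c("angle_deg", "intensity", "timer_positive"), "cell table")
  out <- tibble::as_tibble(cells)
  n <- grid$n_bins
  row <- axis_bin(out$intensity, grid$intensity_min, grid$intensity_max, n)
  col <- axis_bin(out$angle_deg, grid$angle_min, grid$angle_max, n)
  clipped <- out$timer_positive &
    (out$angle_deg < grid$angle_min | out$angle_deg > grid$angle_max |
       out$intensity < grid$intensity_min | out$intensity > grid$intensity_max)
  row[!out$timer_positive] <- NA_integer_
  col[!out$timer_positive] <- NA_integer_
  clipped[!out$timer_positive] <- NA
  out$pixel_row <- as.integer(row)
  out$pixel_col <- as.integer(col)
  out$clipped <- clipped
  out
}

#' Rasterize one sample into a density image
#'
#' 2D histogram of (angle, intensity) over Timer+ cells on a shared grid.
#' The final bin on each axis is right-edge inclusive, so cells at the grid
#' maximum are kept; cells outside the grid (possible when the grid comes
#' from another cohort) are clipped into the edge bins and counted.
#'
#' @param cells Preprocessed cell table for one sample.
#' @param grid A [timer_grid()].
#' @param as_density If `TRUE` (default) pixels are divided by the number of
#'   cells so the image sums to 1; `FALSE` keeps raw counts.
#' @return A `timer_image`: list with `pixels` (n_bins x n_bins matrix, row
#'   = intensity bin, col = angle bin), `total_cells`, `n_clipped`,
#'   `normalized`, `sample_id`, `grid`.
#' @export
rasterize_sample <- function(cells, grid, as_density = TRUE) {
  idx <- cell_pixel_index(cells, grid)
  pos <- idx[idx$timer_positive, ]
  n <- grid$n_bins
  flat <- pos$pixel_row + n * pos$pixel_col + 1L   # column-major, 1-based
  counts <- tabulate(flat, nbins = n * n)
  pixels <- matrix(counts, nrow = n, ncol = n)
  total <- nrow(pos)
  if (as_density && total > 0) pixels <- pixels / total
  structure(
    list(
      sample_id = if ("sample_id" %in% names(cells) && nrow(cells) > 0)
        cells$sample_id[1] else NA_character_,
      grid = grid,
      pixels = pixels,
      total_cells = total,
      n_clipped = sum(pos$clipped),
      normalized = as_density && total > 0
    ),
    class = "timer_image"
  )
}

#' @export
print.timer_image <- function(x, ...) {
  cat(sprintf("timer_image %s: %d x %d, %d cells (%d clipped), %s\n",
              x$sample_id, nrow(x$pixels), ncol(x$pixels), x$total_cells,
              x$n_clipped, if (x$normalized) "density" else "counts"))
  invisible(x)
}

#' Rasterize every sample of a cohort
#'
#' @param cells Preprocessed multi-sample cell table (needs `sample_id`).
#' @inheritParams rasterize_sample
#' @return Tibble with one row per sample: `sample_id`, `group` (if
#'   present), and a list-column `image` of `timer_image` objects.
#' @export
rasterize_cohort <- function(cells, grid, as_density = TRUE) {
  assert_columns(cells, "sample_id", "cell table")
  keys <- intersect(c("sample_id", "group", "cohort"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      df$sample_id <- key$sample_id
      tibble::tibble(image = list(rasterize_sample(df, grid, as_density)))
    }) |>
    dplyr::ungroup()
}

#' Reverse-map pixels to Angle-Intensity rectangles and member cells
#'
#' Each pixel corresponds to a half-open rectangle in Angle-Intensity space
#' (final bins right-closed). Given a cell table, the cells whose pixel
#' index maps to each queried pixel are returned, enabling per-cell scoring
#' from image-space results.
#'
#' @param pixels Data frame (or matrix) with 0-based columns `pixel_row`,
#'   `pixel_col`.
#' @param grid A [timer_grid()].
#' @param cells Optional preprocessed cell table; when given, a list-column
#'   `cells` holds the member cells of each pixel.
#' @return Tibble with the pixel indices and rectangle bounds
#'   `angle_lo/angle_hi/intensity_lo/intensity_hi`.
#' @export
reverse_map <- function(pixels, grid, cells = NULL) {
  stopifnot(inherits(grid, "timer_grid"))
  px <- tibble::as_tibble(as.data.frame(pixels))
  assert_columns(px, c("pixel_row", "pixel_col"), "pixel set")
  n <- grid$n_bins
  if (any(px$pixel_row < 0 | px$pixel_row >= n | px$pixel_col < 0 | px$pixel_col >= n)) {
    abort(sprintf("pixel indices must lie in [0, %d]", n - 1))
  }
  px$angle_lo <- grid$angle_edges[px$pixel_col + 1]
  px$angle_hi <- grid$angle_edges[px$pixel_col + 2]
  px$intensity_lo <- grid$intensity_edges[px$pixel_row + 1]
  px$intensity_hi <- grid$intensity_edges[px$pixel_row + 2]
  if (!is.null(cells)) {
    idx <- cell_pixel_index(cells, grid)
    px$cells <- purrr::map2(px$pixel_row, px$pixel_col, function(r, c) {
      idx[!is.na(idx$pixel_row) & idx$pixel_row == r & idx$pixel_col == c, ]
    })
  }
  px
}
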