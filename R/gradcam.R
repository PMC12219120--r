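# Gradient-weighted class activation mapping over the attention ConvNet.
#
# For class c with pre-softmax logit y_c and a conv layer's feature maps
# A^k (k channels), the channel weights are the global-average-pooled
# gradients alpha^k_c = (1/Z) sum_ij dy_c/dA^k_ij with Z the pixel count of
# the layer, and the map is ReLU(sum_k alpha^k_c A^k). Per-sample maps of a
# class are summed, normalized to [0,1] and Gaussian-smoothed; differential
# (e.g. WT - KO) maps subtract two aggregated maps.

new_cam_map <- function(map, raw, layer, class, Z, n_samples, provenance,
                        sigma = 0, normalized = FALSE, constant = FALSE) {
  structure(
    list(map = map, raw = raw, layer = layer, class = class, Z = Z,
         n_samples = n_samples, sigma = sigma, normalized = normalized,
         constant = constant, provenance = provenance),
    class = "cam_map"
  )
}

#' @export
print.cam_map <- function(x, ...) {
  cat(sprintf("cam_map [%s, class %s]: %d x %d (Z = %d), %d sample(s), %s\n",
              x$layer, x$class, nrow(x$map), ncol(x$map), x$Z, x$n_samples,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

# Bilinear (or nearest) 1D interpolation matrix from n_in to n_out pixel
# centres; upsampling a map is Wr %*% X %*% t(Wc).
interp_matrix <- function(n_in, n_out, method = "bilinear") {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    c_in <- (o - 0.5) * scale + 0.5
    if (method == "nearest") {
      M[o, min(max(round(c_in), 1), n_in)] <- 1
    } else {
      i0 <- floor(c_in)
      w <- c_in - i0
      i0 <- min(max(i0, 1), n_in)
      i1 <- min(i0 + 1, n_in)
      M[o, i0] <- M[o, i0] + (1 - w)
      M[o, i1] <- M[o, i1] + w
    }
  }
  M
}

#' Grad-CAM heatmap of one sample
#'
#' Computes the class-activation map of a single image at a named
#' convolutional layer, using the exact backpropagated gradient of the
#' pre-softmax class logit, and bilinearly upsamples it to the input grid
#' resolution.
#'
#' @param model Trained [convnet_build()] model.
#' @param image Image (matrix / `timer_image`).
#' @param layer Layer name from [convnet_layers()].
#' @param class Class label (softmax head); ignored for sigmoid-head models.
#' @param aux Optional aux covariates (single row).
#' @param upsample `"bilinear"` (default) or `"nearest"`.
#' @return A `cam_map` with the upsampled `map`, the layer-resolution
#'   `raw` map, and `Z` (layer pixel count).
#' @export
gradcam_sample <- function(model, image, layer, class = NULL, aux = NULL,
                           upsample = c("bilinear", "nearest")) {
  stopifnot(inherits(model, "tocky_convnet"))
  upsample <- match.arg(upsample)
  if (!layer %in% convnet_layers(model)) {
    abort(sprintf("unknown layer '%s'; valid layers: %s", layer,
                  paste(convnet_layers(model), collapse = ", ")))
  }
  spec <- model$spec
  x <- as_pixel_matrix(image, spec$n_bins)
  A <- prepare_aux(model, aux, 1)
  cache <- nn_forward(model, x, A[1, ])
  if (spec$head == "softmax") {
    ci <- match(as.character(class), model$classes)
    if (is.na(ci)) {
      abort(sprintf("unknown class '%s'; model classes: %s", class,
                    paste(model$classes, collapse = ", ")))
    }
    dlog <- numeric(spec$n_classes)
    dlog[ci] <- 1
  } else {
    dlog <- 1
  }
  g <- nn_backward(model, cache, dlog, stop_layer = layer)
  act <- cache_activation(model, cache, layer)
  Z <- nrow(act)
  alpha <- colMeans(g$activation)               # (1/Z) sum_ij dy_c/dA^k_ij
  L <- relu(drop(act %*% alpha))
  dims <- layer_dims(model, layer)
  raw <- matrix(L, dims["H"], dims["W"])
  if (dims["H"] == spec$n_bins) {
    up <- raw
  } else {
    M <- interp_matrix(dims["H"], spec$n_bins, upsample)
    up <- M %*% raw %*% t(M)
  }
  cam <- new_cam_map(up, raw, layer, as.character(class %||% "score"), Z,
                     n_samples = 1L, provenance = "gradcam")
  cam$alpha <- alpha
  cam
}

min_max_normalize <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(list(map = m * 0, constant = TRUE))
  list(map = (m - rng[1]) / (rng[2] - rng[1]), constant = FALSE)
}

# Separable Gaussian blur with a normalized truncated kernel (radius 4
# sigma) and zero padding; preserves total mass exactly for maps supported
# away from the borders.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x) {      # along rows (first dimension)
    out <- x * k[r + 1]
    n <- nrow(x)
    for (d in seq_len(min(r, n - 1L))) {
      out[seq_len(n - d), ] <- out[seq_len(n - d), ] +
        k[r + 1 + d] * x[(d + 1):n, , drop = FALSE]
      out[(d + 1):n, ] <- out[(d + 1):n, ] +
        k[r + 1 - d] * x[seq_len(n - d), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Aggregate per-sample Grad-CAM maps of one class
#'
#' Pixel-wise sum over the class's sample maps, then (optionally) min-max
#' normalization to `[0, 1]` and Gaussian smoothing. The processing order
#' is recorded in the provenance so that differently-processed maps are
#' never differenced silently.
#'
#' @param cams List of `cam_map` objects from one layer.
#' @param normalize Min-max normalize the summed map (default TRUE).
#' @param sigma Gaussian smoothing sigma in pixels (default 1; 0 disables).
#' @return Aggregated `cam_map`.
#' @export
aggregate_cams <- function(cams, normalize = TRUE, sigma = 1) {
  stopifnot(length(cams) >= 1, all(vapply(cams, inherits, TRUE, "cam_map")))
  layers <- unique(vapply(cams, `[[`, "", "layer"))
  if (length(layers) != 1) {
    abort(sprintf("cannot aggregate maps from different layers: %s",
                  paste(layers, collapse = ", ")))
  }
  total <- Reduce(`+`, lapply(cams, `[[`, "map"))
  prov <- "sum"
  constant <- FALSE
  if (normalize) {
    nz <- min_max_normalize(total)
    total <- nz$map
    constant <- nz$constant
    if (constant) warn("aggregated map is constant; left as zeros (not divided)")
    prov <- c(prov, "normalize")
  }
  if (sigma > 0) {
    total <- gaussian_smooth(total, sigma)
    prov <- c(prov, sprintf("smooth(sigma=%g)", sigma))
  }
  out <- new_cam_map(total, NULL, layers, cams[[1]]$class, cams[[1]]$Z,
                     n_samples = sum(vapply(cams, `[[`, 1L, "n_samples")),
                     provenance = prov, sigma = sigma,
                     normalized = normalize, constant = constant)
  out
}

#' Aggregated class Grad-CAM over a cohort
#'
#' Convenience wrapper: per-sample Grad-CAM for every image whose label
#' equals `class`, then [aggregate_cams()].
#'
#' @param model Trained model.
#' @param images List/tibble of images (see [convnet_train()]).
#' @param labels Class label per image.
#' @param layer Layer name.
#' @param class Target class.
#' @param aux Optional aux covariates.
#' @inheritParams aggregate_cams
#' @export
gradcam_class <- function(model, images, labels, layer, class, aux = NULL,
                          normalize = TRUE, sigma = 1) {
  if (is.data.frame(images) && "image" %in% names(images)) images <- images$image
  sel <- which(as.character(labels) == as.character(class))
  if (length(sel) == 0) abort(sprintf("no samples with label '%s'", class))
  cams <- lapply(sel, function(i) {
    gradcam_sample(model, images[[i]], layer, class,
                   aux = if (is.null(aux)) NULL else aux[i, , drop = FALSE])
  })
  aggregate_cams(cams, normalize = normalize, sigma = sigma)
}

#' Differential Grad-CAM map
#'
#' Element-wise difference `a - b` of two aggregated maps from the same
#' layer with identical processing provenance (e.g. WT minus KO);
#' antisymmetric under argument swap.
#'
#' @param cam_a,cam_b Aggregated `cam_map` objects.
#' @return A `cam_differential`: the difference `map` (may be negative) and
#'   the provenance of both inputs.
#' @export
gradcam_differential <- function(cam_a, cam_b) {
  stopifnot(inherits(cam_a, "cam_map"), inherits(cam_b, "cam_map"))
  if (!identical(cam_a$layer, cam_b$layer)) {
    abort(sprintf("layer mismatch: %s vs %s", cam_a$layer, cam_b$layer))
  }
  if (!identical(cam_a$provenance, cam_b$provenance)) {
    abort("processing provenance differs between the two maps")
  }
  structure(
    list(map = cam_a$map - cam_b$map, layer = cam_a$layer,
         minuend = cam_a$class, subtrahend = cam_b$class,
         provenance = list(a = cam_a$provenance, b = cam_b$provenance)),
    class = "cam_differential"
  )
}

#' @export
print.cam_differential <- function(x, ...) {
  cat(sprintf("cam_differential [%s]: %s - %s, %d x %d\n", x$layer,
              x$minuend, x$subtrahend, nrow(x$map), ncol(x$map)))
  invisible(x)
}

#' Per-cell Grad-CAM scores
#'
#' Each Timer+ cell inherits the (differential) heatmap value of its pixel
#' under the shared grid; the mapping reuses [cell_pixel_index()], so a
#' model trained on one cohort can score the cells of another as long as
#' the training grid is supplied.
#'
#' @param cam A `cam_map` or `cam_differential` at grid resolution.
#' @param cells Preprocessed cell table.
#' @param grid The [timer_grid()] the model's images were built on.
#' @return Input tibble (Timer+ and Timer- cells retained) with
#'   `cam_score` (`NA` for Timer-negative cells).
#' @export
gradcam_cell_scores <- function(cam, cells, grid) {
  stopifnot(inherits(cam, c("cam_map", "cam_differential")),
            inherits(grid, "timer_grid"))
  if (nrow(cam$map) != grid$n_bins) {
    abort(sprintf("map resolution %d does not match grid n_bins %d",
                  nrow(cam$map), grid$n_bins))
  }
  idx <- cell_pixel_index(cells, grid)
  score <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$pixel_row)
  score[ok] <- cam$map[cbind(idx$pixel_row[ok] + 1L, idx$pixel_col[ok] + 1L)]
  idx$cam_score <- score
  idx
}

#' Select feature cells by score percentile
#'
#' `upper_pct` keeps cells with score at or above the given percentile of
#' the pooled per-cell score distribution (e.g. 90 for the top decile of a
#' WT-KO differential map); `lower_pct` keeps cells at or below it (e.g.
#' 25 for the KO-skewed bottom quarter). Boundary ties are kept.
#'
#' @param scored Cell table with a score column.
#' @param upper_pct,lower_pct Exactly one must be given, in `[0, 100]`.
#' @param score_col Score column name (default `"cam_score"`).
#' @return Tibble of selected cells with attributes `"threshold"` and
#'   `"rule"`.
#' @export
feature_cells_by_percentile <- function(scored, upper_pct = NULL,
                                        lower_pct = NULL,
                                        score_col = "cam_score") {
  assert_columns(scored, score_col, "scored cell table")
  if (is.null(upper_pct) == is.null(lower_pct)) {
    abort("give exactly one of upper_pct or lower_pct")
  }
  s <- scored[[score_col]]
  if (all(is.na(s))) abort("empty score vector")
  if (!is.null(upper_pct)) {
    thr <- upper_percentile_cut(s[!is.na(s)], upper_pct)
    keep <- !is.na(s) & s >= thr
    rule <- sprintf("top %gth percentile of %s", upper_pct, score_col)
  } else {
    thr <- upper_percentile_cut(s[!is.na(s)], lower_pct)
    keep <- !is.na(s) & s <= thr
    rule <- sprintf("bottom %gth percentile of %s", lower_pct, score_col)
  }
  out <- scored[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "rule") <- rule
  out
}

#' Layer-wise class discrimination by Grad-CAM feature cells
#'
#' For each class, aggregates that class's Grad-CAM at the given layer,
#' scores every cell of the cohort, selects feature cells at the
#' percentile, and uses each sample's fraction of feature cells as its
#' score; one-vs-rest ROC AUC per class summarises how class-discriminative
#' the layer is.
#'
#' @param model Trained model.
#' @param images Tibble from [rasterize_cohort()] (`sample_id`, `group`,
#'   `image`) or a list of images with `labels`/`sample_ids` given.
#' @param cells Preprocessed cohort cell table.
#' @param grid Shared [timer_grid()].
#' @param layer Layer name.
#' @param percentile Upper feature-cell percentile (default 90).
#' @param sigma,normalize Aggregation settings (see [aggregate_cams()]).
#' @param aux Optional aux covariates.
#' @return List: `sample_scores` tibble (`sample_id`, `group`, per-class
#'   feature-cell fractions in `[0,1]`) and `auc` tibble (`layer`, `class`,
#'   `auc`).
#' @export
layer_discrimination <- function(model, images, cells, grid, layer,
                                 percentile = 90, sigma = 1,
                                 normalize = TRUE, aux = NULL) {
  stopifnot(is.data.frame(images), all(c("sample_id", "group", "image") %in% names(images)))
  classes <- unique(images$group)
  scores <- tibble::tibble(sample_id = images$sample_id, group = images$group)
  aucs <- list()
  for (cl in classes) {
    if (!cl %in% model$classes) {
      warn(sprintf("class '%s' unknown to the model; skipped", cl))
      next
    }
    cam <- gradcam_class(model, images, images$group, layer, cl,
                         aux = aux, normalize = normalize, sigma = sigma)
    scored <- gradcam_cell_scores(cam, cells, grid)
    feats <- feature_cells_by_percentile(scored, upper_pct = percentile)
    thr <- attr(feats, "threshold")
    frac <- scored |>
      dplyr::filter(.data$timer_positive) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(frac = mean(.data$cam_score >= thr), .groups = "drop")
    col <- paste0("frac_", cl)
    scores[[col]] <- frac$frac[match(scores$sample_id, frac$sample_id)]
    aucs[[cl]] <- tibble::tibble(
      layer = layer, class = cl,
      auc = rank_auc(scores[[col]], scores$group == cl))
  }
  list(sample_scores = scores, auc = dplyr::bind_rows(aucs))
}
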