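# TockyConvNet-style compact spatial-attention ConvNets, implemented from
# first principles (forward, backprop, Adam) so that intermediate feature
# maps and exact gradients are available to Grad-CAM.

#' Specify an attention ConvNet architecture
#'
#' Each block applies a 3x3 same-padded convolution with ReLU, then a
#' sigmoid-activated pointwise (1x1) convolution producing a single-channel
#' spatial attention map A which multiplicatively gates the feature maps
#' (Y = X * A, broadcast over channels), then 2x2 max pooling and dropout.
#' Blocks are stacked `n_blocks` times; the flattened features (optionally
#' concatenated with standardized auxiliary scalars such as %Timer+ of
#' parent or age) feed the head: a dense ReLU layer with dropout 0.5 and a
#' softmax output for classification, or a single sigmoid-activated dense
#' unit for a continuous score.
#'
#' @param n_bins Input image resolution (images are n_bins x n_bins x 1).
#' @param n_blocks Number of conv-attention blocks (1, 2 or 3).
#' @param filters Conv filters per block (recycled; default 32).
#' @param n_classes Number of classes (softmax head).
#' @param head `"softmax"` (classifier) or `"sigmoid"` (continuous score).
#' @param dense_units Width of the dense layer before the softmax head.
#' @param dropout_block Dropout rate after each block (default 0.25).
#' @param dropout_final Dropout before the softmax output (fixed 0.5 by
#'   default).
#' @param aux_inputs Character vector naming auxiliary scalar covariates.
#' @param input_scale Fixed multiplicative rescaling of input pixels before
#'   the first convolution. The default `NULL` uses `n_bins^2`, which maps a
#'   per-sample density image (pixels summing to 1) to mean pixel magnitude
#'   ~1 so gradients are well-scaled; pass 1 for raw count images.
#' @return A `convnet_spec` object.
#' @export
convnet_spec <- function(n_bins = 100, n_blocks = 2, filters = 32,
                         n_classes = 2, head = c("softmax", "sigmoid"),
                         dense_units = 64, dropout_block = 0.25,
                         dropout_final = 0.5, aux_inputs = character(0),
                         input_scale = NULL) {
  head <- match.arg(head)
  if (!n_blocks %in% 1:3) abort("n_blocks must be 1, 2 or 3")
  stopifnot(n_bins >= 4, n_classes >= 2 || head == "sigmoid",
            dense_units >= 1, dropout_block >= 0, dropout_block < 1,
            dropout_final >= 0, dropout_final < 1)
  filters <- rep_len(filters, n_blocks)
  structure(
    list(n_bins = as.integer(n_bins), n_blocks = as.integer(n_blocks),
         filters = as.integer(filters), n_classes = as.integer(n_classes),
         head = head, dense_units = as.integer(dense_units),
         dropout_block = dropout_block, dropout_final = dropout_final,
         aux_inputs = aux_inputs,
         input_scale = input_scale %||% as.numeric(n_bins)^2),
    class = "convnet_spec"
  )
}

#' Build an (untrained) attention ConvNet
#'
#' Instantiates Glorot-uniform parameters and precomputes the convolution
#' and pooling index geometry for the given [convnet_spec()].
#'
#' @param spec A [convnet_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `tocky_convnet` model object.
#' @export
convnet_build <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "convnet_spec"))
  geom <- list()
  H <- spec$n_bins
  cin <- 1L
  for (b in seq_len(spec$n_blocks)) {
    cout <- spec$filters[b]
    g <- list(H = H, W = H, cin = cin, cout = cout,
              idx = conv3_indices(H, H), pidx = pool2_indices(H, H),
              Hp = H %/% 2L)
    geom[[b]] <- g
    H <- g$Hp
    cin <- cout
  }
  flat_dim <- H * H * cin
  n_aux <- length(spec$aux_inputs)
  params <- list()
  withr::with_seed(child_seed(seed, 17L), {
    for (b in seq_len(spec$n_blocks)) {
      g <- geom[[b]]
      params[[paste0("conv_W", b)]] <-
        matrix(glorot(9 * g$cin, 9 * g$cout, c(9 * g$cin, g$cout)), 9 * g$cin, g$cout)
      params[[paste0("conv_b", b)]] <- numeric(g$cout)
      params[[paste0("attn_W", b)]] <-
        matrix(glorot(g$cout, 1, c(g$cout, 1)), g$cout, 1)
      params[[paste0("attn_b", b)]] <- 0
    }
    if (spec$head == "softmax") {
      params$dense_W <- matrix(glorot(flat_dim + n_aux, spec$dense_units,
                                      c(flat_dim + n_aux, spec$dense_units)),
                               flat_dim + n_aux, spec$dense_units)
      params$dense_b <- numeric(spec$dense_units)
      params$out_W <- matrix(glorot(spec$dense_units, spec$n_classes,
                                    c(spec$dense_units, spec$n_classes)),
                             spec$dense_units, spec$n_classes)
      params$out_b <- numeric(spec$n_classes)
    } else {
      params$out_W <- matrix(glorot(flat_dim + n_aux, 1,
                                    c(flat_dim + n_aux, 1)),
                             flat_dim + n_aux, 1)
      params$out_b <- 0
    }
  })
  structure(
    list(spec = spec, geom = geom, flat_dim = flat_dim, params = params,
         classes = NULL, aux_center = NULL, aux_scale = NULL,
         trained = FALSE, history = NULL, seed = seed),
    class = "tocky_convnet"
  )
}

#' @export
print.tocky_convnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "tocky_convnet: %d block(s), %d x %d input, %s head, %s parameters%s\n",
    x$spec$n_blocks, x$spec$n_bins, x$spec$n_bins, x$spec$head,
    format(np, big.mark = ","),
    if (x$trained) " (trained)" else " (untrained)"))
  if (length(x$spec$aux_inputs)) {
    cat("  aux inputs:", paste(x$spec$aux_inputs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convolutional layer names of a model
#'
#' `convN` is the ReLU output of block N's 3x3 convolution; `attnN` is the
#' attention-modulated feature map Y of block N.
#' @param model A `tocky_convnet`.
#' @return Character vector of valid Grad-CAM layer names.
#' @export
convnet_layers <- function(model) {
  b <- seq_len(model$spec$n_blocks)
  as.vector(rbind(paste0("conv", b), paste0("attn", b)))
}

# Coerce an image argument (timer_image, matrix, or vector) to the
# (n_bins^2) x 1 column-major pixel matrix the network consumes.
as_pixel_matrix <- function(image, n_bins) {
  if (inherits(image, "timer_image")) image <- image$pixels
  if (is.matrix(image)) {
    if (nrow(image) != n_bins || ncol(image) != n_bins) {
      abort(sprintf("image is %d x %d but the model expects %d x %d",
                    nrow(image), ncol(image), n_bins, n_bins))
    }
    return(matrix(as.vector(image), ncol = 1))
  }
  if (length(image) != n_bins^2) abort("image length does not match the grid")
  matrix(as.numeric(image), ncol = 1)
}

# Full forward pass for one sample. `aux` is the standardized aux vector
# (possibly length 0). Dropout masks are drawn only when training = TRUE.
nn_forward <- function(model, x, aux = numeric(0), training = FALSE) {
  spec <- model$spec
  p <- model$params
  x <- x * spec$input_scale
  cache <- list(blocks = vector("list", spec$n_blocks))
  for (b in seq_len(spec$n_blocks)) {
    g <- model$geom[[b]]
    P <- im2col3(x, g$idx)
    Zc <- P %*% p[[paste0("conv_W", b)]]
    Zc <- sweep(Zc, 2, p[[paste0("conv_b", b)]], "+")
    Xr <- relu(Zc)
    az <- drop(Xr %*% p[[paste0("attn_W", b)]]) + p[[paste0("attn_b", b)]]
    A <- sigmoid(az)
    Y <- Xr * A
    mp <- maxpool_forward(Y, g$pidx)
    out <- mp$out
    dmask <- NULL
    if (training && spec$dropout_block > 0) {
      dmask <- (matrix(runif(length(out)), nrow(out)) >= spec$dropout_block) /
        (1 - spec$dropout_block)
      out <- out * dmask
    }
    cache$blocks[[b]] <- list(P = P, Zc = Zc, Xr = Xr, A = A, Y = Y,
                              arg = mp$arg, dmask = dmask, out = out)
    x <- out
  }
  flat <- c(as.vector(x), aux)
  cache$flat <- flat
  if (spec$head == "softmax") {
    h_pre <- drop(crossprod(p$dense_W, flat)) + p$dense_b
    h <- relu(h_pre)
    hmask <- NULL
    if (training && spec$dropout_final > 0) {
      hmask <- (runif(length(h)) >= spec$dropout_final) / (1 - spec$dropout_final)
      h <- h * hmask
    }
    logits <- drop(crossprod(p$out_W, h)) + p$out_b
    cache <- c(cache, list(h_pre = h_pre, h = h, hmask = hmask,
                           logits = logits, probs = softmax_vec(logits)))
  } else {
    z <- drop(crossprod(p$out_W, flat)) + p$out_b
    cache <- c(cache, list(logits = z, probs = sigmoid(z)))
  }
  cache
}

# Backward pass from a gradient on the logits. Returns parameter gradients
# and, when `stop_layer` names a conv/attn feature map, also the gradient
# of the seeded scalar w.r.t. that activation (backprop halts there).
nn_backward <- function(model, cache, dlogits, stop_layer = NULL) {
  spec <- model$spec
  p <- model$params
  grads <- list()
  n_aux <- length(spec$aux_inputs)
  if (spec$head == "softmax") {
    grads$out_W <- cache$h %o% dlogits
    grads$out_b <- dlogits
    dh <- drop(p$out_W %*% dlogits)
    if (!is.null(cache$hmask)) dh <- dh * cache$hmask
    dh <- dh * (cache$h_pre > 0)
    grads$dense_W <- cache$flat %o% dh
    grads$dense_b <- dh
    dflat <- drop(p$dense_W %*% dh)
  } else {
    dz <- as.numeric(dlogits)
    grads$out_W <- matrix(cache$flat * dz, ncol = 1)
    grads$out_b <- dz
    dflat <- drop(p$out_W) * dz
  }
  if (n_aux > 0) dflat <- dflat[seq_len(length(dflat) - n_aux)]
  g_last <- model$geom[[spec$n_blocks]]
  dx <- matrix(dflat, nrow = g_last$Hp^2, ncol = g_last$cout)
  for (b in rev(seq_len(spec$n_blocks))) {
    g <- model$geom[[b]]
    cb <- cache$blocks[[b]]
    if (!is.null(cb$dmask)) dx <- dx * cb$dmask
    dY <- maxpool_backward(dx, cb$arg, g$pidx, g$H * g$W)
    if (identical(stop_layer, paste0("attn", b))) {
      grads$activation <- dY
      return(grads)
    }
    # Y = Xr * A (A broadcast over channels)
    dXr_gate <- dY * cb$A
    dA <- rowSums(dY * cb$Xr)
    daz <- dA * cb$A * (1 - cb$A)
    grads[[paste0("attn_W", b)]] <- matrix(drop(crossprod(cb$Xr, daz)), ncol = 1)
    grads[[paste0("attn_b", b)]] <- sum(daz)
    dXr <- dXr_gate + daz %o% drop(p[[paste0("attn_W", b)]])
    if (identical(stop_layer, paste0("conv", b))) {
      grads$activation <- dXr
      return(grads)
    }
    dZc <- dXr * (cb$Zc > 0)
    grads[[paste0("conv_W", b)]] <- crossprod(cb$P, dZc)
    grads[[paste0("conv_b", b)]] <- colSums(dZc)
    if (b > 1) {
      dP <- tcrossprod(dZc, p[[paste0("conv_W", b)]])
      dx <- col2im3(dP, g$idx, g$cin)
    }
  }
  if (!is.null(stop_layer)) {
    abort(sprintf("unknown layer '%s'; valid layers: %s", stop_layer,
                  paste(convnet_layers(model), collapse = ", ")))
  }
  grads
}

# Retrieve a named feature map (post-activation) from a forward cache.
cache_activation <- function(model, cache, layer) {
  b <- as.integer(sub("^(conv|attn)", "", layer))
  kind <- sub("[0-9]+$", "", layer)
  if (is.na(b) || b < 1 || b > model$spec$n_blocks || !kind %in% c("conv", "attn")) {
    abort(sprintf("unknown layer '%s'; valid layers: %s", layer,
                  paste(convnet_layers(model), collapse = ", ")))
  }
  if (kind == "conv") cache$blocks[[b]]$Xr else cache$blocks[[b]]$Y
}

layer_dims <- function(model, layer) {
  b <- as.integer(sub("^(conv|attn)", "", layer))
  g <- model$geom[[b]]
  c(H = g$H, W = g$W)
}

prepare_aux <- function(model, aux, n_images) {
  spec <- model$spec
  n_aux <- length(spec$aux_inputs)
  if (n_aux == 0) return(matrix(0, n_images, 0))
  if (is.null(aux)) {
    abort(sprintf("model requires aux covariate(s): %s",
                  paste(spec$aux_inputs, collapse = ", ")))
  }
  aux <- as.matrix(as.data.frame(aux)[, spec$aux_inputs, drop = FALSE])
  if (nrow(aux) != n_images) abort("aux rows must match the number of images")
  ctr <- model$aux_center %||% rep(0, n_aux)
  scl <- model$aux_scale %||% rep(1, n_aux)
  sweep(sweep(aux, 2, ctr, "-"), 2, scl, "/")
}

extract_images <- function(images, n_bins) {
  if (is.data.frame(images) && "image" %in% names(images)) images <- images$image
  lapply(images, as_pixel_matrix, n_bins = n_bins)
}

#' Train an attention ConvNet
#'
#' Minimises categorical (softmax head) or binary (sigmoid head)
#' cross-entropy with the Adam optimiser. Dropout is active during training
#' only; inference is deterministic.
#'
#' @param model A [convnet_build()] model (or a trained one to continue).
#' @param images List of n_bins x n_bins matrices, `timer_image` objects,
#'   or a tibble from [rasterize_cohort()].
#' @param labels Class labels (factor/character) for the softmax head, or
#'   numeric targets in `[0, 1]` for the sigmoid head.
#' @param aux Optional data frame of auxiliary scalars (one row per image)
#'   holding the columns named in the spec's `aux_inputs`; standardized
#'   with training-set statistics.
#' @param epochs,batch_size,learning_rate Training protocol; defaults 12,
#'   4 and 0.001 (the protocol sweeps 10-12 epochs, batches 4-8, rates
#'   0.001-0.002). Values outside those ranges are accepted with a warning.
#' @param validation Optional list `list(images =, labels =, aux =)` used to
#'   monitor held-out accuracy per epoch.
#' @param seed Integer seed (shuffling, dropout).
#' @param verbose Print per-epoch metrics.
#' @return The trained model; per-epoch metrics in `model$history`.
#' @export
convnet_train <- function(model, images, labels, aux = NULL, epochs = 12,
                          batch_size = 4, learning_rate = 0.001,
                          validation = NULL, seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "tocky_convnet"))
  spec <- model$spec
  if (epochs < 10 || epochs > 12 || batch_size < 4 || batch_size > 8 ||
      learning_rate < 0.001 || learning_rate > 0.002) {
    warn("training hyperparameters outside the default protocol ranges (epochs 10-12, batch 4-8, lr 0.001-0.002)")
  }
  xs <- extract_images(images, spec$n_bins)
  n <- length(xs)
  if (spec$head == "softmax") {
    y <- factor(labels)
    if (nlevels(y) != spec$n_classes) {
      abort(sprintf("spec expects %d classes but labels have %d levels",
                    spec$n_classes, nlevels(y)))
    }
    model$classes <- levels(y)
    yi <- as.integer(y)
  } else {
    yv <- as.numeric(labels)
    stopifnot(all(yv >= 0 & yv <= 1))
  }
  n_aux <- length(spec$aux_inputs)
  if (n_aux > 0 && is.null(model$aux_center)) {
    a_raw <- as.matrix(as.data.frame(aux)[, spec$aux_inputs, drop = FALSE])
    model$aux_center <- colMeans(a_raw)
    sds <- apply(a_raw, 2, sd)
    sds[sds == 0 | is.na(sds)] <- 1
    model$aux_scale <- sds
  }
  A <- prepare_aux(model, aux, n)
  state <- adam_init(model$params)
  hist <- list()
  withr::with_seed(child_seed(seed, 19L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      correct <- 0
      for (start in seq(1, n, by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1, n)]
        grads_sum <- NULL
        for (i in bidx) {
          cache <- nn_forward(model, xs[[i]], A[i, ], training = TRUE)
          if (spec$head == "softmax") {
            pr <- cache$probs
            losses <- c(losses, -log(max(pr[yi[i]], 1e-12)))
            correct <- correct + (which.max(pr) == yi[i])
            dlog <- pr
            dlog[yi[i]] <- dlog[yi[i]] - 1
          } else {
            pr <- cache$probs
            losses <- c(losses, -(yv[i] * log(max(pr, 1e-12)) +
                                    (1 - yv[i]) * log(max(1 - pr, 1e-12))))
            correct <- correct + ((pr > 0.5) == (yv[i] > 0.5))
            dlog <- pr - yv[i]
          }
          g <- nn_backward(model, cache, dlog)
          grads_sum <- if (is.null(grads_sum)) g else {
            for (nm in names(g)) grads_sum[[nm]] <- grads_sum[[nm]] + g[[nm]]
            grads_sum
          }
        }
        for (nm in names(grads_sum)) grads_sum[[nm]] <- grads_sum[[nm]] / length(bidx)
        upd <- adam_step(model$params, grads_sum, state, learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      row <- tibble::tibble(epoch = ep, loss = mean(losses), accuracy = correct / n)
      if (!is.null(validation)) {
        vm <- convnet_eval(model, validation$images, validation$labels,
                           validation$aux)
        row$val_loss <- vm$loss
        row$val_accuracy <- vm$accuracy
      }
      hist[[ep]] <- row
      if (verbose) {
        cat(sprintf("epoch %2d  loss %.4f  acc %.3f%s\n", ep, row$loss,
                    row$accuracy,
                    if (!is.null(validation))
                      sprintf("  val_loss %.4f  val_acc %.3f",
                              row$val_loss, row$val_accuracy) else ""))
      }
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model
}

# Deterministic evaluation (dropout off).
convnet_eval <- function(model, images, labels, aux = NULL) {
  spec <- model$spec
  xs <- extract_images(images, spec$n_bins)
  A <- prepare_aux(model, aux, length(xs))
  loss <- 0
  correct <- 0
  if (spec$head == "softmax") {
    yi <- as.integer(factor(labels, levels = model$classes))
    for (i in seq_along(xs)) {
      pr <- nn_forward(model, xs[[i]], A[i, ])$probs
      loss <- loss - log(max(pr[yi[i]], 1e-12))
      correct <- correct + (which.max(pr) == yi[i])
    }
  } else {
    yv <- as.numeric(labels)
    for (i in seq_along(xs)) {
      pr <- nn_forward(model, xs[[i]], A[i, ])$probs
      loss <- loss - (yv[i] * log(max(pr, 1e-12)) +
                        (1 - yv[i]) * log(max(1 - pr, 1e-12)))
      correct <- correct + ((pr > 0.5) == (yv[i] > 0.5))
    }
  }
  list(loss = loss / length(xs), accuracy = correct / length(xs))
}

#' Predict from a trained attention ConvNet
#'
#' @param object A trained `tocky_convnet`.
#' @param images As in [convnet_train()].
#' @param aux Optional aux covariate data frame.
#' @param type `"prob"` (default; class probabilities summing to 1),
#'   `"class"`, `"logit"` (pre-softmax class scores -- the continuous-score
#'   readout obtained by dropping the softmax), or `"score"` (sigmoid-head
#'   scalar in (0,1)).
#' @param ... Unused.
#' @return A tibble of predictions, one row per image.
#' @export
predict.tocky_convnet <- function(object, images, aux = NULL,
                                  type = c("prob", "class", "logit", "score"),
                                  ...) {
  type <- match.arg(type)
  spec <- object$spec
  xs <- extract_images(images, spec$n_bins)
  A <- prepare_aux(object, aux, length(xs))
  if (spec$head == "sigmoid") {
    sc <- vapply(seq_along(xs), function(i)
      as.numeric(nn_forward(object, xs[[i]], A[i, ])$probs), numeric(1))
    lg <- vapply(seq_along(xs), function(i)
      as.numeric(nn_forward(object, xs[[i]], A[i, ])$logits), numeric(1))
    return(tibble::tibble(.score = if (type == "logit") lg else sc))
  }
  out <- purrr::map_dfr(seq_along(xs), function(i) {
    cache <- nn_forward(object, xs[[i]], A[i, ])
    tibble::as_tibble(setNames(as.list(cache$probs),
                               paste0(".prob_", object$classes))) |>
      dplyr::bind_cols(tibble::as_tibble(setNames(as.list(cache$logits),
                                                  paste0(".logit_", object$classes))))
  })
  out$.pred_class <- object$classes[max.col(as.matrix(
    out[, paste0(".prob_", object$classes)]), ties.method = "first")]
  switch(type,
         prob = out[, c(paste0(".prob_", object$classes), ".pred_class")],
         class = out[, ".pred_class", drop = FALSE],
         logit = out[, paste0(".logit_", object$classes)],
         score = abort("type = 'score' applies to sigmoid-head models"))
}

#' Three-fold cross-validated ConvNet training
#'
#' Stratified k-fold cross-validation of an attention ConvNet: each fold
#' trains a fresh model on the remaining folds and monitors accuracy on the
#' held-out fold; a final model is then refit on all samples.
#'
#' @inheritParams convnet_train
#' @param spec A [convnet_spec()].
#' @param folds Number of folds (default 3).
#' @return A `tocky_convnet_cv` list: `fold_history` (per fold/epoch
#'   metrics), `cv_accuracy` (mean final-epoch validation accuracy),
#'   `fold_accuracy`, the refit `model`, and the fold assignment.
#' @export
convnet_crossval <- function(spec, images, labels, aux = NULL, folds = 3,
                             epochs = 12, batch_size = 4,
                             learning_rate = 0.001, seed = 1,
                             verbose = FALSE) {
  stopifnot(inherits(spec, "convnet_spec"))
  if (is.data.frame(images) && "image" %in% names(images)) images <- images$image
  n <- length(images)
  y <- factor(labels)
  if (any(table(y) < folds)) {
    abort(sprintf("stratified %d-fold CV needs >= %d samples per class", folds, folds))
  }
  fold_of <- integer(n)
  withr::with_seed(child_seed(seed, 23L), {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  hist <- list()
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    m <- convnet_build(spec, seed = child_seed(seed, 29L + f))
    m <- convnet_train(
      m, images[tr], labels[tr],
      aux = if (is.null(aux)) NULL else aux[tr, , drop = FALSE],
      epochs = epochs, batch_size = batch_size,
      learning_rate = learning_rate,
      validation = list(images = images[va], labels = labels[va],
                        aux = if (is.null(aux)) NULL else aux[va, , drop = FALSE]),
      seed = child_seed(seed, 37L + f), verbose = verbose)
    h <- m$history
    h$fold <- f
    hist[[f]] <- h
    fold_acc[f] <- h$val_accuracy[nrow(h)]
  }
  final <- convnet_build(spec, seed = child_seed(seed, 41L))
  final <- convnet_train(final, images, labels, aux = aux, epochs = epochs,
                         batch_size = batch_size,
                         learning_rate = learning_rate,
                         seed = child_seed(seed, 43L), verbose = verbose)
  structure(
    list(fold_history = dplyr::bind_rows(hist),
         fold_accuracy = fold_acc,
         cv_accuracy = mean(fold_acc),
         model = final, fold_of = fold_of),
    class = "tocky_convnet_cv"
  )
}

#' @export
print.tocky_convnet_cv <- function(x, ...) {
  cat(sprintf("tocky_convnet_cv: %d folds, CV accuracy %.3f (per fold: %s)\n",
              length(x$fold_accuracy), x$cv_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = ", ")))
  invisible(x)
}

#' Quadratic regression of model scores on log2 age
#'
#' Fits `score ~ poly(log2(age), 2)` by least squares (optionally per
#' organ) and reports the fit alongside a raw-age quadratic for R-squared
#' comparison; continuous Timer scores across ontogeny are better described
#' on the log-age scale.
#'
#' @param data Data frame with a score column and an age column (days > 0);
#'   optional `organ` column fits one model per organ.
#' @param score_col,age_col Column names.
#' @return A `timer_score_fit`: tibble of per-organ fits with coefficients,
#'   `r_squared_log` and `r_squared_raw`, plus the `lm` objects.
#' @export
fit_score_regression <- function(data, score_col = "score", age_col = "age_days") {
  assert_columns(data, c(score_col, age_col), "score table")
  if (any(data[[age_col]] <= 0)) abort("ages must be positive")
  if (length(unique(data[[age_col]])) < 4) abort("need >= 4 distinct ages")
  groups <- if ("organ" %in% names(data)) split(data, data$organ) else list(all = data)
  fits <- purrr::imap(groups, function(df, nm) {
    la <- log2(df[[age_col]])
    fit_log <- lm(df[[score_col]] ~ la + I(la^2))
    ra <- df[[age_col]]
    fit_raw <- lm(df[[score_col]] ~ ra + I(ra^2))
    # summary() warns on numerically perfect fits; R-squared is still valid
    r2 <- function(f) suppressWarnings(summary(f)$r.squared)
    list(organ = nm, fit = fit_log,
         row = tibble::tibble(
           organ = nm,
           intercept = coef(fit_log)[1],
           linear = coef(fit_log)[2],
           quadratic = coef(fit_log)[3],
           r_squared_log = r2(fit_log),
           r_squared_raw = r2(fit_raw)))
  })
  structure(
    list(table = purrr::map_dfr(fits, "row"),
         models = purrr::map(fits, "fit")),
    class = "timer_score_fit"
  )
}

#' @export
print.timer_score_fit <- function(x, ...) {
  print(x$table)
  invisible(x)
}
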