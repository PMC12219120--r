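# Correctness of the hand-rolled network against independent oracles.

test_that("backpropagated gradients match central finite differences", {
  spec <- convnet_spec(n_bins = 10, n_blocks = 2, filters = 3, n_classes = 2,
                       dense_units = 5, aux_inputs = "a1", input_scale = 1)
  m <- convnet_build(spec, seed = 2)
  m$aux_center <- 0
  m$aux_scale <- 1
  withr::with_seed(4, x <- matrix(runif(100), 10, 10))
  xv <- timerflow:::as_pixel_matrix(x, 10)
  A <- timerflow:::prepare_aux(m, data.frame(a1 = 0.4), 1)
  cache <- timerflow:::nn_forward(m, xv, A[1, ])
  yi <- 2
  dlog <- cache$probs
  dlog[yi] <- dlog[yi] - 1
  g <- timerflow:::nn_backward(m, cache, dlog)
  loss <- function(mm) -log(timerflow:::nn_forward(mm, xv, A[1, ])$probs[yi])
  eps <- 1e-4
  withr::with_seed(5, {
    for (nm in names(m$params)) {
      for (ii in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
        m2 <- m; m2$params[[nm]][ii] <- m$params[[nm]][ii] + eps
        m3 <- m; m3$params[[nm]][ii] <- m$params[[nm]][ii] - eps
        num <- (loss(m2) - loss(m3)) / (2 * eps)
        expect_equal(g[[nm]][ii], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("attention saturation gives the identity and null limits", {
  spec <- convnet_spec(n_bins = 8, n_blocks = 1, filters = 2, n_classes = 2,
                       dense_units = 4, input_scale = 1)
  m <- convnet_build(spec, seed = 1)
  withr::with_seed(6, x <- matrix(runif(64), 8, 8))
  xv <- timerflow:::as_pixel_matrix(x, 8)
  m$params$attn_W1[] <- 0
  m$params$attn_b1 <- 30            # sigmoid ~ 1: Y ~ X
  c1 <- timerflow:::nn_forward(m, xv)
  expect_equal(c1$blocks[[1]]$Y, c1$blocks[[1]]$Xr, tolerance = 1e-10)
  m$params$attn_b1 <- -30           # sigmoid ~ 0: Y ~ 0
  c0 <- timerflow:::nn_forward(m, xv)
  expect_lt(max(abs(c0$blocks[[1]]$Y)), 1e-10)
  expect_true(all(c1$blocks[[1]]$A > 0 & c1$blocks[[1]]$A < 1))
})

test_that("same-padded convolution and pooling match a naive implementation", {
  H <- 6
  withr::with_seed(7, {
    x <- matrix(rnorm(H * H), H, H)
    w <- array(rnorm(9), c(3, 3))
  })
  idx <- timerflow:::conv3_indices(H, H)
  P <- timerflow:::im2col3(matrix(as.vector(x), ncol = 1), idx)
  Wm <- matrix(as.vector(w), 9, 1)   # rows: (di, dj) column-major like conv3_indices
  got <- matrix(P %*% Wm, H, H)
  ref <- matrix(0, H, H)
  for (i in 1:H) for (j in 1:H) {
    acc <- 0
    for (dj in -1:1) for (di in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= H) {
        acc <- acc + w[di + 2, dj + 2] * x[ii, jj]
      }
    }
    ref[i, j] <- acc
  }
  expect_equal(got, ref, tolerance = 1e-12)
  pidx <- timerflow:::pool2_indices(H, H)
  pooled <- timerflow:::maxpool_forward(matrix(as.vector(x), ncol = 1), pidx)
  ref_pool <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    ref_pool[i, j] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(matrix(pooled$out, 3, 3), ref_pool)
})

test_that("parameter counts match a hand count of the default architecture", {
  m <- convnet_build(convnet_spec(n_bins = 100, n_blocks = 2, filters = 32,
                                  n_classes = 2, dense_units = 64), seed = 1)
  counts <- vapply(m$params, length, integer(1))
  # conv1 9*1*32+32; attn1 32+1; conv2 9*32*32+32; attn2 32+1;
  # dense (25*25*32)*64+64; out 64*2+2
  expect_equal(sum(counts), 320 + 33 + 9248 + 33 + (20000 * 64 + 64) + 130)
  expect_equal(m$flat_dim, 25 * 25 * 32)
})

test_that("the 4-class variant differs from the 2-class only in head width", {
  m2 <- convnet_build(convnet_spec(n_bins = 20, n_classes = 2), seed = 1)
  m4 <- convnet_build(convnet_spec(n_bins = 20, n_classes = 4), seed = 1)
  shared <- setdiff(names(m2$params), c("out_W", "out_b"))
  for (nm in shared) expect_equal(dim2 <- dim(m2$params[[nm]]), dim(m4$params[[nm]]))
  expect_equal(ncol(m2$params$out_W), 2)
  expect_equal(ncol(m4$params$out_W), 4)
})

test_that("the aux-input variant is a parameter superset of the image-only model", {
  m0 <- convnet_build(convnet_spec(n_bins = 16), seed = 1)
  ma <- convnet_build(convnet_spec(n_bins = 16, aux_inputs = c("pct_timer", "age")),
                      seed = 1)
  expect_equal(nrow(ma$params$dense_W), nrow(m0$params$dense_W) + 2)
  expect_equal(names(m0$params), names(ma$params))
})

test_that("inference is deterministic and probabilities behave", {
  spec <- convnet_spec(n_bins = 12, n_blocks = 1, filters = 4, n_classes = 3,
                       dense_units = 8)
  m <- convnet_build(spec, seed = 3)
  m$classes <- c("x", "y", "z")
  m$trained <- TRUE
  withr::with_seed(8, img <- matrix(runif(144), 12, 12))
  p1 <- predict(m, list(img))
  p2 <- predict(m, list(img))
  expect_identical(p1, p2)
  expect_equal(p1$.prob_x + p1$.prob_y + p1$.prob_z, 1)
  # sigmoid head lives in (0, 1)
  ms <- convnet_build(convnet_spec(n_bins = 12, n_blocks = 1, filters = 4,
                                   head = "sigmoid"), seed = 4)
  ms$trained <- TRUE
  s <- predict(ms, list(img))$.score
  expect_true(s > 0 && s < 1)
})

test_that("2-class logit scores rank samples exactly like softmax probabilities", {
  m <- convnet_build(convnet_spec(n_bins = 12, n_blocks = 1, filters = 4,
                                  n_classes = 2, dense_units = 8), seed = 5)
  m$classes <- c("neg", "pos")
  m$trained <- TRUE
  withr::with_seed(9, imgs <- replicate(12, matrix(runif(144), 12, 12),
                                        simplify = FALSE))
  pr <- predict(m, imgs, type = "prob")
  lg <- predict(m, imgs, type = "logit")
  margin <- lg$.logit_pos - lg$.logit_neg
  expect_equal(order(pr$.prob_pos), order(margin))
  # exact algebraic link: p = sigmoid(logit difference)
  expect_equal(pr$.prob_pos, 1 / (1 + exp(-margin)), tolerance = 1e-12)
})
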