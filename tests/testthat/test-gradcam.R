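test_that("alpha equals the closed-form gradient of the linear toy network", {
  m <- linear_toy_model()
  x <- matrix(seq_len(16) / 10, 4, 4)  # unique max in each pool cell
  cam <- gradcam_sample(m, x, "conv1", "c1")
  # dy1/dXr is 0.5 * w_q at each pool cell's argmax (bottom-right corners
  # here), so alpha = mean = 0.5 * sum(w) / 16
  expect_identical(cam$Z, 16L)
  expect_equal(unname(cam$alpha), 0.5 * (0.1 + 0.2 + 0.3 + 0.4) / 16,
               tolerance = 1e-14)
  # map = ReLU(alpha * A) with A = x itself (identity conv, ReLU inactive)
  expect_equal(cam$raw, unname(cam$alpha) * x, tolerance = 1e-14)
})

test_that("negative-only contributions are zeroed by the ReLU", {
  m <- linear_toy_model(out_sign = -1)
  x <- matrix(seq_len(16) / 10, 4, 4)
  cam <- gradcam_sample(m, x, "conv1", "c1")
  expect_lt(unname(cam$alpha), 0)
  expect_equal(cam$raw, matrix(0, 4, 4))
})

test_that("unknown layers and classes are rejected with guidance", {
  m <- linear_toy_model()
  x <- matrix(1:16 / 10, 4, 4)
  expect_error(gradcam_sample(m, x, "conv9", "c1"), "valid layers")
  expect_error(gradcam_sample(m, x, "conv1", "zzz"), "model classes")
})

test_that("aggregation normalizes to [0,1], is scale-invariant, and sigma 0 is identity", {
  m <- linear_toy_model()
  withr::with_seed(41, {
    cams <- lapply(1:3, function(i) {
      gradcam_sample(m, matrix(runif(16), 4, 4), "conv1", "c1")
    })
  })
  agg <- aggregate_cams(cams, normalize = TRUE, sigma = 0)
  expect_equal(min(agg$map), 0)
  expect_equal(max(agg$map), 1)
  # single map: aggregation is identity up to normalization
  one <- aggregate_cams(cams[1], normalize = TRUE, sigma = 0)
  nz <- cams[[1]]$map - min(cams[[1]]$map)
  expect_equal(one$map, nz / max(nz))
  # duplicating the sample list leaves the min-max-normalized map unchanged
  dup <- aggregate_cams(c(cams, cams), normalize = TRUE, sigma = 0)
  expect_equal(dup$map, agg$map, tolerance = 1e-12)
  # constant map flagged, not divided by zero
  cc <- cams[1:2]
  cc[[1]]$map[] <- 1
  cc[[2]]$map[] <- 1
  expect_warning(flat <- aggregate_cams(cc, normalize = TRUE, sigma = 0),
                 "constant")
  expect_true(flat$constant)
  expect_true(all(is.finite(flat$map)))
})

test_that("Gaussian smoothing preserves the mass of interior-supported maps", {
  m0 <- matrix(0, 30, 30)
  withr::with_seed(42, m0[12:19, 12:19] <- runif(64))
  for (sigma in c(0.5, 1, 2)) {
    sm <- timerflow:::gaussian_smooth(m0, sigma)
    expect_equal(sum(sm), sum(m0), tolerance = 1e-9)
  }
  expect_identical(timerflow:::gaussian_smooth(m0, 0), m0)
})

test_that("differential maps subtract, anti-commute and check provenance", {
  m <- linear_toy_model()
  withr::with_seed(43, {
    cams_a <- lapply(1:2, function(i) gradcam_sample(m, matrix(runif(16), 4, 4),
                                                     "conv1", "c1"))
    cams_b <- lapply(1:2, function(i) gradcam_sample(m, matrix(runif(16), 4, 4),
                                                     "conv1", "c1"))
  })
  a <- aggregate_cams(cams_a, sigma = 1)
  b <- aggregate_cams(cams_b, sigma = 1)
  d <- gradcam_differential(a, b)
  expect_equal(d$map, a$map - b$map)
  d2 <- gradcam_differential(b, a)
  expect_equal(d2$map, -d$map)
  self <- gradcam_differential(a, a)
  expect_true(all(self$map == 0))
  b_other <- aggregate_cams(cams_b, sigma = 2)
  expect_error(gradcam_differential(a, b_other), "provenance")
})

test_that("per-cell CAM scores are a pixel lookup", {
  withr::with_seed(44, {
    cells <- cells_from_polar(runif(400, 0, 90), runif(400, 0.01, 1))
  })
  g <- timer_grid(cells, n_bins = 10)
  cam <- structure(list(map = matrix(runif(100), 10, 10), layer = "conv1",
                        class = "c1", provenance = "test"),
                   class = "cam_map")
  scored <- gradcam_cell_scores(cam, cells, g)
  idx <- cell_pixel_index(cells, g)
  pick <- withr::with_seed(45, sample(400, 100))
  for (i in pick) {
    expect_equal(scored$cam_score[i],
                 cam$map[idx$pixel_row[i] + 1, idx$pixel_col[i] + 1])
  }
  # constant map: every cell equal; shared pixels share scores
  cam$map[] <- 0.7
  sc2 <- gradcam_cell_scores(cam, cells, g)
  expect_true(all(sc2$cam_score == 0.7))
  cam_small <- cam
  cam_small$map <- matrix(1, 5, 5)
  expect_error(gradcam_cell_scores(cam_small, cells, g), "resolution")
})

test_that("percentile feature-cell selection handles upper and lower tails", {
  sc <- tibble::tibble(cell_id = 1:200, cam_score = seq(0, 1, length.out = 200))
  up <- feature_cells_by_percentile(sc, upper_pct = 90)
  expect_equal(nrow(up), 20)
  lo <- feature_cells_by_percentile(sc, lower_pct = 25)
  expect_equal(nrow(lo), 50)
  expect_true(all(lo$cam_score <= quantile(sc$cam_score, 0.25)))
  all_cells <- feature_cells_by_percentile(sc, upper_pct = 0)
  expect_equal(nrow(all_cells), 200)
  expect_error(feature_cells_by_percentile(sc), "exactly one")
  expect_error(feature_cells_by_percentile(sc, upper_pct = 10, lower_pct = 10),
               "exactly one")
})

test_that("a model trained on one cohort scores another cohort's cells on the shared grid", {
  fix <- blob_images(6, n_bins = 16, seed = 46)
  spec <- convnet_spec(n_bins = 16, n_blocks = 1, filters = 6, n_classes = 2,
                       dense_units = 8)
  m <- convnet_build(spec, seed = 47)
  m <- convnet_train(m, fix$images, fix$labels, epochs = 10, seed = 48)
  cam <- gradcam_class(m, fix$images, fix$labels, "conv1", "A", sigma = 1)
  # an unseen cohort, same grid
  withr::with_seed(49, {
    other <- cells_from_polar(runif(500, 1, 89), runif(500, 0.05, 0.95))
  })
  g <- timer_grid(cells_from_polar(c(0, 90), c(0.01, 1)), n_bins = 16)
  scored <- gradcam_cell_scores(cam, other, g)
  expect_equal(sum(is.na(scored$cam_score)), 0)
  expect_true(all(scored$cam_score >= 0))
})
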