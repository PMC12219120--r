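# Shared fixtures, built once per test run.

# A small two-group cohort (WT-like vs reduced-burst-frequency KO-like).
small_cohort <- function(n_samples = 4, cells = 600, seed = 42) {
  simulate_timer_cohort(
    groups = list(
      timer_group_spec("WT", n_samples = n_samples, cells_per_sample = cells),
      timer_group_spec("KO", n_samples = n_samples, cells_per_sample = cells,
                       burst_frequency_per_week = 0.5)
    ),
    seed = seed
  )
}

# Matched negative control for threshold estimation.
negative_control <- function(n = 2000, model = measurement_model(), seed = 99) {
  withr::with_seed(seed, measure_cells(
    tibble::tibble(blue_molecules = numeric(n), red_molecules = numeric(n)),
    model
  ))
}

preprocessed_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- small_cohort()
      thr <- estimate_thresholds(negative_control())
      cache <<- preprocess_timer(coh, thr)
    }
    cache
  }
})

# Minimal preprocessed-like table built directly from angle/intensity.
cells_from_polar <- function(angle_deg, intensity, sample_id = "s1") {
  tibble::tibble(
    cell_id = sprintf("c%04d", seq_along(angle_deg)),
    sample_id = sample_id,
    blue_norm = intensity * cospi(angle_deg / 180),
    red_norm = intensity * sinpi(angle_deg / 180),
    timer_positive = TRUE,
    angle_deg = angle_deg,
    intensity = intensity
  )
}

# All permutations of 1..n (n small), for brute-force assignment oracles.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force LSAP: minimal sum_i D[i, p(i)] over all permutations.
brute_force_lsap <- function(D) {
  k <- nrow(D)
  best <- Inf
  best_p <- NULL
  for (p in all_permutations(k)) {
    cost <- sum(D[cbind(seq_len(k), p)])
    if (cost < best) {
      best <- cost
      best_p <- p
    }
  }
  list(cost = best, perm = best_p)
}

# A hand-built linear chain: conv passes the input through (identity
# kernel), attention is exactly 0.5 (zero weights and bias), pooling picks
# known maxima, and the class-1 logit is a known linear functional of the
# feature map. Every Grad-CAM quantity is then available in closed form.
linear_toy_model <- function(out_sign = 1) {
  spec <- convnet_spec(n_bins = 4, n_blocks = 1, filters = 1, n_classes = 2,
                       dense_units = 1, input_scale = 1)
  m <- convnet_build(spec, seed = 1)
  m$params$conv_W1[] <- 0
  m$params$conv_W1[5, 1] <- 1          # centre tap: identity convolution
  m$params$conv_b1[] <- 0
  m$params$attn_W1[] <- 0
  m$params$attn_b1 <- 0                # sigmoid(0) = 1/2 exactly
  m$params$dense_W[] <- c(0.1, 0.2, 0.3, 0.4)
  m$params$dense_b[] <- 0
  m$params$out_W[] <- c(out_sign, 0)   # logit_1 = sign * h, logit_2 = 0
  m$params$out_b[] <- 0
  m$classes <- c("c1", "c2")
  m$trained <- TRUE
  m
}

# Gaussian-blob density images for quick ConvNet checks.
blob_images <- function(n_per_class, n_bins = 20, centers = c(0.3, 0.7),
                        points = 250, sd_frac = 0.12, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(cx) {
      replicate(n_per_class, {
        i <- pmin(n_bins, pmax(1, round(rnorm(points, n_bins / 2, sd_frac * n_bins))))
        j <- pmin(n_bins, pmax(1, round(rnorm(points, cx * n_bins, sd_frac * n_bins))))
        m <- matrix(0, n_bins, n_bins)
        for (q in seq_len(points)) m[i[q], j[q]] <- m[i[q], j[q]] + 1
        m / points
      }, simplify = FALSE)
    }
    list(images = c(mk(centers[1]), mk(centers[2])),
         labels = rep(c("A", "B"), each = n_per_class))
  })
}
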