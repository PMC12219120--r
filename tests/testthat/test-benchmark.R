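test_that("gates classify archetypal cells and respect the diagonal tie rule", {
  cells <- tibble::tibble(
    sample_id = "s1",
    blue_norm = c(0.5, 0.4, 0.0, 0.0, 0.3),
    red_norm = c(0.0, 0.6, 0.5, 0.0, 0.3),
    timer_positive = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  cells <- transform_polar(cells)
  gf <- apply_gates(cells)
  expect_equal(gf$pct_blue_pos_red_neg, 20)
  expect_equal(gf$pct_blue_pos_red_pos, 40)
  expect_equal(gf$pct_blue_neg_red_pos, 20)
  expect_equal(gf$pct_double_neg, 20)
  # diagonal cell (0.3, 0.3) goes to Red(high) by the >= rule
  expect_equal(gf$pct_polygon_red_high, 40)   # (0.4,0.6) and (0.3,0.3)
  expect_equal(gf$pct_polygon_blue_high, 20)  # (0.5,0)
  # all Blue-only cells: 100% in the Blue+Red- quadrant
  blue_only <- transform_polar(tibble::tibble(
    sample_id = "s2", blue_norm = runif(10, 0.1, 1), red_norm = 0,
    timer_positive = TRUE))
  expect_equal(apply_gates(blue_only)$pct_blue_pos_red_neg, 100)
})

test_that("gate percentages match a brute-force per-cell evaluation", {
  withr::with_seed(51, {
    cells <- tibble::tibble(
      sample_id = rep(c("a", "b"), each = 200),
      blue_norm = pmax(0, rnorm(400, 0.3, 0.25)),
      red_norm = pmax(0, rnorm(400, 0.3, 0.25)))
  })
  cells$timer_positive <- cells$blue_norm > 0 | cells$red_norm > 0
  cells <- transform_polar(cells)
  gf <- apply_gates(cells)
  a <- cells[cells$sample_id == "a", ]
  expect_equal(gf$pct_polygon_blue_high[gf$sample_id == "a"],
               100 * sum(a$blue_norm > 0 & a$blue_norm > a$red_norm) / nrow(a))
  expect_equal(gf$pct_timer_pos[gf$sample_id == "a"],
               100 * mean(a$timer_positive))
  expect_equal(gf$mean_angle[gf$sample_id == "a"],
               mean(a$angle_deg[a$timer_positive]))
})

test_that("mean Timer Angle averages Timer+ cells and flags empty samples", {
  cells <- cells_from_polar(rep(45, 10), rep(0.5, 10))
  expect_equal(mean_timer_angle(cells)$mean_angle, 45)
  half <- cells_from_polar(c(rep(0, 5), rep(90, 5)), rep(0.5, 10))
  expect_equal(mean_timer_angle(half)$mean_angle, 45)
  none <- tibble::tibble(sample_id = "s", angle_deg = NA_real_,
                         timer_positive = FALSE)
  mt <- mean_timer_angle(none)
  expect_true(mt$flag_no_timer)
  expect_true(is.na(mt$mean_angle))
})

test_that("logistic gate classifier is perfect on label-identical features and null on noise", {
  withr::with_seed(52, {
    n <- 40
    tab <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:n),
      group = rep(c("KO", "WT"), n / 2),
      pct_timer_pos = runif(n, 40, 60))
    tab$pct_polygon_blue_high <- ifelse(tab$group == "WT", 30, 10) + rnorm(n, 0, 0.5)
  })
  suppressWarnings(fit <- logistic_gate_classifier(tab[1:20, ], tab[21:40, ]))
  expect_equal(fit$metrics$auc, 1)
  expect_gte(fit$accuracy, 0.95)
  # label-independent features: chance-level AUC across many test samples
  withr::with_seed(53, {
    null_tab <- tibble::tibble(
      sample_id = sprintf("n%03d", 1:300),
      group = rep(c("KO", "WT"), 150),
      pct_timer_pos = runif(300, 40, 60),
      pct_polygon_blue_high = runif(300, 10, 30))
  })
  nf <- logistic_gate_classifier(null_tab[1:100, ], null_tab[101:300, ])
  expect_gt(nf$metrics$auc, 0.35)
  expect_lt(nf$metrics$auc, 0.65)
  one_group <- tab
  one_group$group <- "WT"
  expect_error(logistic_gate_classifier(one_group, tab), "2 groups")
})

test_that("ROC and average precision hit the analytic extremes", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  perf <- evaluate_roc_pr(scores, labels)
  expect_equal(perf$auc, 1)
  expect_equal(perf$average_precision, 1)
  rev_perf <- evaluate_roc_pr(-scores, labels)
  expect_equal(rev_perf$auc, 0)
  expect_error(evaluate_roc_pr(scores, rep(TRUE, 6)), "positive and one negative")
})

test_that("random scores give chance AUC and agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(54, {
    scores <- runif(1000)
    labels <- rep(c(TRUE, FALSE), 500)
  })
  perf <- evaluate_roc_pr(scores, labels)
  expect_gt(perf$auc, 0.45)
  expect_lt(perf$auc, 0.55)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(perf$auc, ref, tolerance = 1e-12)
})

test_that("multiclass evaluation macro-averages one-vs-rest", {
  withr::with_seed(55, {
    lab <- rep(c("a", "b", "c"), each = 20)
    sc <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
    sc[cbind(seq_len(60), match(lab, c("a", "b", "c")))] <- sc[cbind(seq_len(60), match(lab, c("a", "b", "c")))] + 2
  })
  perf <- evaluate_roc_pr(sc, lab)
  expect_equal(perf$auc, 1)
  expect_length(perf$per_class, 3)
})

test_that("display helpers return ggplot objects", {
  pp <- preprocessed_cohort()
  g <- timer_grid(pp, n_bins = 20)
  im <- rasterize_sample(pp[pp$sample_id == pp$sample_id[1], ], g)
  expect_s3_class(autoplot(im), "ggplot")
  expect_s3_class(plot_timer_scatter(pp), "ggplot")
  perf <- evaluate_roc_pr(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_s3_class(plot_roc(perf), "ggplot")
})
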