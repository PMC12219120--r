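test_that("k = 1 collapses to one cluster at the standardized mean", {
  pp <- preprocessed_cohort()
  km <- tocky_kmeans(pp, k = 1, seed = 1)
  expect_true(all(km$cells$cluster == 1))
  expect_equal(unname(km$centroids[1, ]), c(0, 0), tolerance = 1e-9)
})

test_that("well-separated blobs are recovered and seeding is deterministic", {
  skip_if_not_installed("mclust")
  withr::with_seed(13, {
    truth <- rep(1:3, each = 300)
    ang <- c(rnorm(300, 10, 0.5), rnorm(300, 45, 0.5), rnorm(300, 80, 0.5))
    int <- c(rnorm(300, 0.2, 0.005), rnorm(300, 0.5, 0.005), rnorm(300, 0.9, 0.005))
  })
  cells <- cells_from_polar(pmin(pmax(ang, 0), 90), pmax(int, 0.01))
  km <- tocky_kmeans(cells, k = 3, seed = 4)
  expect_gt(mclust::adjustedRandIndex(km$cells$cluster, truth), 0.99)
  km2 <- tocky_kmeans(cells, k = 3, seed = 4)
  expect_identical(km$cells$cluster, km2$cells$cluster)
  expect_error(tocky_kmeans(cells[1:2, ], k = 5), "exceeds")
})

test_that("cluster percentage rows sum to 100 and match direct tabulation", {
  pp <- preprocessed_cohort()
  km <- tocky_kmeans(pp, k = 6, seed = 2)
  tab <- cluster_percentages(km)
  feats <- grep("^cluster_", names(tab), value = TRUE)
  expect_equal(unname(rowSums(tab[, feats])), rep(100, nrow(tab)), tolerance = 1e-6)
  s1 <- tab$sample_id[1]
  direct <- 100 * table(factor(km$cells$cluster[km$cells$sample_id == s1], levels = 1:6)) /
    sum(km$cells$sample_id == s1)
  expect_equal(unname(unlist(tab[1, feats])), unname(as.numeric(direct)),
               tolerance = 1e-9)
})

test_that("Hungarian matching equals brute-force enumeration and recovers swaps", {
  pp <- preprocessed_cohort()
  tr <- pp[pp$cohort == "train", ]
  km_tr <- tocky_kmeans(tr, k = 5, seed = 1)
  # self-match: identity, zero cost
  self <- match_clusters(km_tr, km_tr)
  expect_equal(self$assignment, 1:5)
  expect_equal(self$cost, 0)
  # swapped clusters: permutation recovers the swap
  km_sw <- km_tr
  swap <- c(2, 1, 3, 4, 5)
  km_sw$medians <- km_tr$medians[swap, ]
  sw <- match_clusters(km_tr, km_sw)
  expect_equal(sw$assignment, order(swap))
  expect_equal(sw$cost, 0, tolerance = 1e-12)
  # random medians: cost equals exhaustive minimum for k <= 6
  withr::with_seed(17, {
    for (k in 2:6) {
      a <- km_tr
      b <- km_tr
      a$k <- b$k <- k
      a$medians <- cbind(angle = rnorm(k), intensity = rnorm(k))
      b$medians <- cbind(angle = rnorm(k), intensity = rnorm(k))
      m <- match_clusters(a, b)
      bf <- brute_force_lsap(m$D)
      expect_equal(m$cost, bf$cost, tolerance = 1e-12)
    }
  })
  km_other <- tocky_kmeans(tr, k = 4, seed = 1)
  expect_error(match_clusters(km_tr, km_other), "differ")
})

test_that("random forest finds the discriminating cluster and errors on bad input", {
  withr::with_seed(19, {
    n <- 12
    base <- matrix(20, 2 * n, 5)
    base[, 5] <- 20
    base[1:n, 2] <- 35; base[1:n, 5] <- 5          # group difference in cluster 2
    noise <- matrix(runif(10 * n, -2, 2), 2 * n, 5)
    x <- base + noise
    x <- 100 * x / rowSums(x)
  })
  tab <- tibble::as_tibble(setNames(as.data.frame(x), sprintf("cluster_%02d", 1:5)))
  tab$sample_id <- sprintf("s%02d", 1:(2 * n))
  tab$group <- rep(c("hi", "lo"), each = n)
  rf <- tocky_rf(tab, n_trees = 200, seed = 5)
  expect_lt(rf$oob_error, 0.2)
  expect_equal(names(which.max(rf$mdg)), "cluster_02")
  expect_true(all(rf$mdg >= 0))
  # resubstitution on separable data is near-perfect; probabilities sum to 1
  met <- rf_test_metrics(rf, tab)
  expect_gte(met$accuracy, 0.95)
  pred <- predict(rf, tab)
  expect_equal(unname(pred$.prob_hi + pred$.prob_lo), rep(1, 2 * n))
  # single class rejected
  tab_one <- tab; tab_one$group <- "same"
  expect_error(tocky_rf(tab_one), ">= 2 groups")
})

test_that("identically distributed groups give chance-level out-of-bag error", {
  withr::with_seed(23, {
    x <- matrix(runif(24 * 6, 10, 30), 24, 6)
    x <- 100 * x / rowSums(x)
  })
  tab <- tibble::as_tibble(setNames(as.data.frame(x), sprintf("cluster_%02d", 1:6)))
  tab$sample_id <- sprintf("s%02d", 1:24)
  tab$group <- rep(c("a", "b"), 12)
  rf <- tocky_rf(tab, n_trees = 300, seed = 6)
  expect_gt(rf$oob_error, 0.25)
})

test_that("per-cell MDG scores are constant within cluster and rank like the MDG", {
  pp <- preprocessed_cohort()
  tr <- pp[pp$cohort == "train", ]
  te <- pp[pp$cohort == "test", ]
  km_tr <- tocky_kmeans(tr, k = 6, seed = 1)
  km_te <- apply_cluster_match(tocky_kmeans(te, k = 6, seed = 2),
                               match_clusters(km_tr, tocky_kmeans(te, k = 6, seed = 2)))
  rf <- tocky_rf(cluster_percentages(km_tr), n_trees = 200, seed = 3)
  sc <- mdg_cell_scores(rf, km_te)
  per_cluster <- tapply(sc$score, sc$cluster, function(v) length(unique(v)))
  expect_true(all(per_cluster == 1))
  cluster_scores <- tapply(sc$score, sc$cluster, unique)
  expect_equal(unname(rank(cluster_scores)),
               unname(rank(rf$mdg[sprintf("cluster_%02d", as.integer(names(cluster_scores)))])))
})

test_that("percentile feature-cell extraction keeps boundary ties", {
  sc <- tibble::tibble(cell_id = 1:100, score = 1:100)
  expect_equal(nrow(extract_feature_cells(sc, 0)), 100)
  top <- extract_feature_cells(sc, 100)
  expect_equal(top$score, 100)
  mid <- extract_feature_cells(sc, 60)
  expect_equal(nrow(mid), 40)
  expect_equal(min(mid$score), 61)
  # when the threshold lands on a tied value, all tied cells are kept
  tied <- tibble::tibble(cell_id = 1:100, score = c(rep(1, 60), rep(2, 40)))
  kept <- extract_feature_cells(tied, 70)
  expect_equal(attr(kept, "threshold"), 2)
  expect_equal(nrow(kept), 40)
  flat <- tibble::tibble(cell_id = 1:10, score = rep(2, 10))
  expect_warning(all_kept <- extract_feature_cells(flat, 60), "ties")
  expect_equal(nrow(all_kept), 10)
})

test_that("DBSCAN separates blobs, degenerates to noise, ignores input order", {
  withr::with_seed(29, {
    pts <- rbind(cbind(rnorm(200, 0, 0.5), rnorm(200, 0, 0.5)),
                 cbind(rnorm(200, 10, 0.5), rnorm(200, 10, 0.5)))
  })
  lab <- dbscan_points(pts, eps = 1, min_pts = 10)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
  expect_lt(mean(lab == 0), 0.05)
  tiny <- dbscan_points(pts, eps = 1e-9, min_pts = 3)
  expect_true(all(tiny == 0))
  perm <- withr::with_seed(30, sample.int(nrow(pts)))
  lab_p <- dbscan_points(pts[perm, ], eps = 1, min_pts = 10)
  # same partition up to label names
  expect_equal(length(unique(paste(lab[perm], lab_p))),
               length(unique(lab_p)))
  feats <- cells_from_polar(c(rep(10, 30), rep(80, 30)) + rnorm(60, 0, 0.5),
                            rep(0.5, 60))
  out <- density_cluster_features(feats, eps = 0.5, min_pts = 5)
  expect_equal(length(setdiff(unique(out$density_cluster), 0L)), 2)
  expect_error(density_cluster_features(feats[0, ]), "empty")
})

test_that("tidiers expose MDG rankings and match diagnostics", {
  pp <- preprocessed_cohort()
  km <- tocky_kmeans(pp[pp$cohort == "train", ], k = 4, seed = 1)
  rf <- tocky_rf(cluster_percentages(km), n_trees = 100, seed = 2)
  td <- tidy(rf)
  expect_equal(names(td), c("term", "mdg"))
  expect_false(is.unsorted(rev(td$mdg)))
  gl <- glance(rf)
  expect_equal(gl$n_trees, 100)
  mt <- match_clusters(km, km)
  expect_equal(glance(mt)$cost, 0)
  expect_equal(nrow(tidy(mt)), 4)
})
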