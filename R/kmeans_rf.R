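# TockyKmeansRF-style pipeline: k-means clustering of Timer Angle/Intensity,
# cross-dataset cluster matching by linear sum assignment, Random-Forest
# classification of cluster-percentage tables, and per-cell MDG scores.

# z-score standardization of (angle, intensity) over Timer+ cells.
standardize_coords <- function(cells) {
  pos <- cells[cells$timer_positive, , drop = FALSE]
  mu <- c(angle = mean(pos$angle_deg), intensity = mean(pos$intensity))
  sdv <- c(angle = sd(pos$angle_deg), intensity = sd(pos$intensity))
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(
    z = cbind(angle = (pos$angle_deg - mu["angle"]) / sdv["angle"],
              intensity = (pos$intensity - mu["intensity"]) / sdv["intensity"]),
    cells = pos, mean = mu, sd = sdv
  )
}

#' k-means clustering of a Timer dataset
#'
#' Clusters Timer+ cells in standardized (Angle, Intensity) space with one
#' random start and at most 10 Lloyd-style iterations (the pipeline's fixed
#' k-means configuration); training and test datasets are clustered
#' independently and matched afterwards with [match_clusters()].
#'
#' @param cells Preprocessed cell table (needs `angle_deg`, `intensity`,
#'   `timer_positive`, `sample_id`).
#' @param k Number of clusters (default 18).
#' @param seed Integer seed for the random start.
#' @return A `tocky_kmeans` object: clustered cell tibble (`cluster`
#'   column), centroids and medians in standardized space, and the
#'   standardization used.
#' @export
tocky_kmeans <- function(cells, k = 18, seed = 1) {
  assert_columns(cells, c("angle_deg", "intensity", "timer_positive", "sample_id"),
                 "cell table")
  std <- standardize_coords(cells)
  if (nrow(std$z) < k) {
    abort(sprintf("k = %d exceeds the %d Timer+ cells available", k, nrow(std$z)))
  }
  km <- withr::with_seed(child_seed(seed, 11L),
    suppressWarnings(kmeans(std$z, centers = k, nstart = 1, iter.max = 10)))
  out <- std$cells
  out$cluster <- km$cluster
  medians <- t(vapply(seq_len(k), function(i) {
    c(angle = median(std$z[km$cluster == i, "angle"]),
      intensity = median(std$z[km$cluster == i, "intensity"]))
  }, numeric(2)))
  structure(
    list(k = as.integer(k), cells = out, centroids = km$centers,
         medians = medians, standardization = std[c("mean", "sd")],
         seed = seed),
    class = "tocky_kmeans"
  )
}

#' @export
print.tocky_kmeans <- function(x, ...) {
  cat(sprintf("tocky_kmeans: k = %d over %d Timer+ cells, %d samples\n",
              x$k, nrow(x$cells), length(unique(x$cells$sample_id))))
  invisible(x)
}

#' Per-sample cluster percentage table
#'
#' @param model A [tocky_kmeans()] result.
#' @return Tibble, one row per sample: `sample_id`, `group` (if present)
#'   and columns `cluster_01 ... cluster_k` holding the percentage of the
#'   sample's Timer+ cells in each cluster (rows sum to 100). Samples with
#'   no Timer+ cells are absent by construction (they carry no clustered
#'   cells) and are reported in the `"dropped_samples"` attribute when the
#'   source table is supplied via `all_samples`.
#' @param all_samples Optional character vector of expected sample ids used
#'   to flag samples that contributed no Timer+ cells.
#' @export
cluster_percentages <- function(model, all_samples = NULL) {
  stopifnot(inherits(model, "tocky_kmeans"))
  cells <- model$cells
  keys <- intersect(c("sample_id", "group", "cohort"), names(cells))
  tab <- cells |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$cluster) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    dplyr::mutate(cluster = sprintf("cluster_%02d", .data$cluster)) |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "pct",
                       values_fill = 0)
  want <- sprintf("cluster_%02d", seq_len(model$k))
  for (w in setdiff(want, names(tab))) tab[[w]] <- 0
  tab <- tab[, c(keys, want)]
  if (!is.null(all_samples)) {
    dropped <- setdiff(all_samples, tab$sample_id)
    if (length(dropped)) {
      warn(sprintf("%d sample(s) had no Timer+ cells: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
    }
    attr(tab, "dropped_samples") <- dropped
  }
  tab
}

#' Match clusters across datasets by linear sum assignment
#'
#' Each dataset's clusters are summarised by their representative point
#' (median standardized angle, median standardized intensity); the k x k
#' Euclidean distance matrix D between training and test representative
#' points is assigned by the Hungarian method, finding the permutation P
#' minimising trace(DP). Test clusters are then relabelled to their matched
#' training cluster.
#'
#' @param train_model,test_model [tocky_kmeans()] results with equal `k`.
#' @return A `cluster_match`: `m_train`, `m_test` (k x 2 medians), `D`,
#'   `assignment` (integer vector: test cluster assigned to each train
#'   cluster), `test_to_train` (relabelling map) and total `cost`.
#' @export
match_clusters <- function(train_model, test_model) {
  stopifnot(inherits(train_model, "tocky_kmeans"),
            inherits(test_model, "tocky_kmeans"))
  if (train_model$k != test_model$k) {
    abort(sprintf("cluster counts differ: train k = %d, test k = %d",
                  train_model$k, test_model$k))
  }
  k <- train_model$k
  m_tr <- train_model$medians
  m_te <- test_model$medians
  D <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    sqrt(sum((m_tr[i, ] - m_te[j, ])^2))
  }))
  sol <- clue::solve_LSAP(D)
  assignment <- as.integer(sol)                  # train i -> test assignment[i]
  test_to_train <- order(assignment)             # test j -> train test_to_train[j]
  structure(
    list(m_train = m_tr, m_test = m_te, D = D,
         assignment = assignment,
         test_to_train = test_to_train,
         cost = sum(D[cbind(seq_len(k), assignment)])),
    class = "cluster_match"
  )
}

#' @export
print.cluster_match <- function(x, ...) {
  cat(sprintf("cluster_match: k = %d, total cost %.4g\n",
              length(x$assignment), x$cost))
  invisible(x)
}

#' Relabel a test clustering to matched training labels
#'
#' @param model Test [tocky_kmeans()] object.
#' @param match [match_clusters()] result.
#' @return The model with clusters relabelled to training cluster ids.
#' @export
apply_cluster_match <- function(model, match) {
  stopifnot(inherits(model, "tocky_kmeans"), inherits(match, "cluster_match"))
  model$cells$cluster <- match$test_to_train[model$cells$cluster]
  model$medians <- model$medians[match$assignment, , drop = FALSE]
  model$centroids <- model$centroids[match$assignment, , drop = FALSE]
  model$matched <- TRUE
  model
}

#' Train a Random Forest on a cluster percentage table
#'
#' @param pct_table Tibble from [cluster_percentages()] with a `group`
#'   column; needs >= 2 groups and >= 2 samples per group.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return A `tocky_rf`: the fitted forest, out-of-bag error, and the mean
#'   decrease Gini (MDG) importance of each cluster feature.
#' @export
tocky_rf <- function(pct_table, n_trees = 500, seed = 1) {
  assert_columns(pct_table, "group", "cluster percentage table")
  feats <- grep("^cluster_", names(pct_table), value = TRUE)
  if (length(feats) == 0) abort("no cluster_* feature columns found")
  y <- factor(pct_table$group)
  if (nlevels(y) < 2) abort("Random Forest training needs >= 2 groups")
  if (any(table(y) < 2)) abort("each group needs >= 2 samples")
  x <- as.data.frame(pct_table[, feats])
  rf <- withr::with_seed(child_seed(seed, 13L),
    randomForest::randomForest(x = x, y = y, ntree = n_trees))
  mdg <- rf$importance[, "MeanDecreaseGini"]
  structure(
    list(rf = rf, n_trees = n_trees,
         oob_error = mean(rf$predicted != y),
         mdg = setNames(as.numeric(mdg), feats),
         levels = levels(y), features = feats, seed = seed),
    class = "tocky_rf"
  )
}

#' @export
print.tocky_rf <- function(x, ...) {
  cat(sprintf("tocky_rf: %d trees, %d cluster features, OOB error %.3g\n",
              x$n_trees, length(x$features), x$oob_error))
  invisible(x)
}

#' Predict group membership for a matched test percentage table
#'
#' @param object A [tocky_rf()] model.
#' @param newdata Cluster percentage table whose columns were relabelled to
#'   the training clusters (see [apply_cluster_match()]).
#' @param ... Unused.
#' @return Tibble with per-sample class probabilities (`.prob_<class>`,
#'   summing to 1) and `.pred_class`.
#' @export
predict.tocky_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    abort(sprintf("test table lacks matched cluster column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  probs <- predict(object$rf, newdata = as.data.frame(newdata[, object$features]),
                   type = "prob")
  out <- newdata[, intersect(c("sample_id", "group", "cohort"), names(newdata))]
  for (lv in colnames(probs)) out[[paste0(".prob_", lv)]] <- probs[, lv]
  out$.pred_class <- colnames(probs)[max.col(probs, ties.method = "first")]
  out
}

#' Test-set metrics for a TockyKmeansRF model
#'
#' @param object A [tocky_rf()] model.
#' @param newdata Matched test percentage table with a `group` column.
#' @return List: `confusion` (table), `accuracy`, `auc` (2-class: ROC AUC
#'   of the second-level probability; multiclass: macro one-vs-rest).
#' @export
rf_test_metrics <- function(object, newdata) {
  pred <- predict(object, newdata)
  truth <- factor(newdata$group, levels = object$levels)
  confusion <- table(truth = truth,
                     predicted = factor(pred$.pred_class, levels = object$levels))
  acc <- mean(pred$.pred_class == as.character(truth))
  aucs <- vapply(object$levels, function(lv) {
    rank_auc(pred[[paste0(".prob_", lv)]], truth == lv)
  }, numeric(1))
  auc <- if (length(object$levels) == 2) aucs[2] else mean(aucs)
  list(confusion = confusion, accuracy = acc, auc = unname(auc),
       per_class_auc = aucs)
}

#' Per-cell importance scores from cluster MDG
#'
#' Every cell inherits the mean decrease Gini of its (matched) cluster;
#' cells of the same cluster share one score.
#'
#' @param rf A [tocky_rf()] model.
#' @param model A (matched) [tocky_kmeans()] object for the scored dataset.
#' @return The model's cell tibble with a `score` column added.
#' @export
mdg_cell_scores <- function(rf, model) {
  stopifnot(inherits(rf, "tocky_rf"), inherits(model, "tocky_kmeans"))
  cells <- model$cells
  feat <- sprintf("cluster_%02d", cells$cluster)
  unknown <- !feat %in% names(rf$mdg)
  if (any(unknown)) {
    warn(sprintf("%d cell(s) in clusters unseen by the forest; scored NA",
                 sum(unknown)))
  }
  cells$score <- unname(rf$mdg[feat])
  cells
}

#' Extract feature cells above a score percentile
#'
#' Selects cells whose importance score is at or above the given percentile
#' of the per-cell score distribution (ties at the boundary are kept).
#'
#' @param scored Cell table with a score column.
#' @param percentile Percentile in `[0, 100]` (default 60, the MDG feature
#'   cell rule).
#' @param score_col Name of the score column.
#' @return Tibble of selected cells; the threshold and rule are attached as
#'   attributes `"threshold"` and `"rule"`.
#' @export
extract_feature_cells <- function(scored, percentile = 60, score_col = "score") {
  assert_columns(scored, score_col, "scored cell table")
  s <- scored[[score_col]]
  if (all(is.na(s))) abort("all scores are NA")
  thr <- upper_percentile_cut(s[!is.na(s)], percentile)
  if (length(unique(s[!is.na(s)])) == 1) {
    warn("all scores equal: percentile threshold keeps every cell (ties kept)")
  }
  out <- scored[!is.na(s) & s >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  attr(out, "rule") <- sprintf("top %gth percentile of %s", percentile, score_col)
  out
}

#' Density-cluster feature cells
#'
#' DBSCAN over the feature cells' standardized (Angle, Intensity)
#' coordinates; noise points get label 0.
#'
#' @param features Feature-cell table with `angle_deg`, `intensity`.
#' @param eps DBSCAN radius in standardized units (default 0.5).
#' @param min_pts Core-point neighbourhood size (default 25).
#' @return Input tibble with `density_cluster` added (0 = noise).
#' @export
density_cluster_features <- function(features, eps = 0.5, min_pts = 25) {
  assert_columns(features, c("angle_deg", "intensity"), "feature cells")
  if (nrow(features) == 0) abort("empty feature-cell set")
  if (nrow(features) < min_pts) {
    abort(sprintf("need >= min_pts = %d feature cells; got %d",
                  min_pts, nrow(features)))
  }
  z <- scale(cbind(features$angle_deg, features$intensity))
  z[is.nan(z)] <- 0
  out <- tibble::as_tibble(features)
  out$density_cluster <- dbscan_points(z, eps, min_pts)
  out
}
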