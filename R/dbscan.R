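#' Density-based spatial clustering (DBSCAN)
#'
#' Classic DBSCAN over 2D points with a grid-bucketed neighbour search
#' (buckets of side `eps`, so all neighbours of a point lie in its 3x3
#' bucket neighbourhood). Core points have at least `min_pts` neighbours
#' (self included) within `eps`; border points join the cluster of the core
#' that reaches them; unreachable points are noise, labelled 0.
#'
#' @param x Two-column numeric matrix or data frame of coordinates.
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster labels (0 = noise).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 10), ncol = 2))
#' table(dbscan_points(pts, eps = 1, min_pts = 5))
dbscan_points <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2, eps > 0, min_pts >= 1)
  n <- nrow(x)
  if (n == 0) abort("empty point set")
  gx <- floor(x[, 1] / eps)
  gy <- floor(x[, 2] / eps)
  key <- paste(gx, gy, sep = ",")
  buckets <- split(seq_len(n), key)
  eps2 <- eps^2
  nbrs <- function(i) {
    ks <- paste(rep(gx[i] + (-1:1), each = 3), gy[i] + (-1:1), sep = ",")
    cand <- unlist(buckets[ks], use.names = FALSE)
    d2 <- (x[cand, 1] - x[i, 1])^2 + (x[cand, 2] - x[i, 2])^2
    cand[d2 <= eps2]
  }
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    ni <- nbrs(i)
    if (length(ni) < min_pts) next       # noise for now (may become border)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- ni[ni != i]
    enq <- logical(n)
    enq[queue] <- TRUE
    enq[i] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nj <- nbrs(j)
        if (length(nj) >= min_pts) {
          new <- nj[!enq[nj] & labels[nj] == 0L]
          if (length(new)) {
            enq[new] <- TRUE
            queue <- c(queue, new)
          }
        }
      }
    }
  }
  labels
}
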