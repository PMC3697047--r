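# Two-cluster control analysis: single-linkage Euclidean clustering of
# (in-silico estimate, in-vivo abundance) point pairs, with per-cluster
# summary statistics and coefficients of variation.

#' Two-cluster single-linkage partition
#'
#' Builds the full single-linkage dendrogram on Euclidean distances
#' (via [stats::hclust()]) and removes the final, largest merge, leaving
#' exactly two clusters. Duplicated points merge at distance zero and so
#' always share a cluster; the partition does not depend on input order
#' (labels are 1 for the cluster containing the first point).
#'
#' @param points Numeric matrix or data.frame, `n x 2` (n >= 2), finite.
#' @return Integer vector of cluster labels (1 or 2).
#' @export
two_cluster_single_linkage <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2L) stop("need at least 2 points", call. = FALSE)
  if (!is.numeric(pts) || any(!is.finite(pts)))
    stop("points must be finite numeric coordinates", call. = FALSE)
  hc <- stats::hclust(stats::dist(pts, method = "euclidean"), method = "single")
  labels <- unname(stats::cutree(hc, k = 2))
  # canonical labelling: cluster of the first point is 1
  if (labels[1] != 1L) labels <- 3L - labels
  labels
}

#' Per-cluster summary statistics
#'
#' For each of the two clusters: size and percentage of points, mean and
#' sd (n-1 denominator) of each coordinate, the Pearson correlation
#' between the coordinates with its significance (undefined for clusters
#' of fewer than 3 points), and the coefficient of variation
#' `C_V = sd / mean * 100%` of the requested coordinate.
#'
#' @param points Numeric `n x 2` matrix or data.frame.
#' @param labels Integer labels from [two_cluster_single_linkage()]
#'   (exactly two distinct values).
#' @param cv_coordinate Which coordinate (1 or 2) the `C_V` is reported
#'   for (default 2, the observed activity axis).
#' @return A data.frame with one row per cluster: `cluster`, `size`,
#'   `percent`, `mean_x`, `sd_x`, `mean_y`, `sd_y`, `r`, `r_alpha`, `cv`.
#' @export
cluster_report <- function(points, labels, cv_coordinate = 2L) {
  pts <- as.matrix(points)
  if (length(labels) != nrow(pts)) stop("labels must match points", call. = FALSE)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("exactly 2 clusters expected", call. = FALSE)
  cv_coordinate <- as.integer(cv_coordinate)
  stopifnot(cv_coordinate %in% c(1L, 2L))
  n <- nrow(pts)
  rows <- lapply(lv, function(l) {
    p <- pts[labels == l, , drop = FALSE]
    m <- colMeans(p)
    s <- apply(p, 2, stats::sd)
    if (nrow(p) >= 3L) {
      ct <- cor_test_pearson(p[, 1], p[, 2])
      r <- ct$statistic; ra <- ct$alpha
    } else {
      r <- NA_real_; ra <- NA_real_
    }
    cv <- if (abs(m[cv_coordinate]) > 0) abs(s[cv_coordinate] / m[cv_coordinate]) * 100 else 0
    if (s[cv_coordinate] == 0) cv <- 0
    data.frame(cluster = l, size = nrow(p), percent = round(100 * nrow(p) / n),
               mean_x = m[1], sd_x = s[1], mean_y = m[2], sd_y = s[2],
               r = r, r_alpha = ra, cv = cv, row.names = NULL)
  })
  do.call(rbind, rows)
}
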