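#' Pairwise Euclidean distance matrix of a point cloud
#'
#' @param points A data frame or numeric matrix with one row per point and one
#'   numeric column per coordinate.
#'
#' @return A symmetric numeric matrix with zero diagonal; entry `(i, j)` is the
#'   Euclidean distance between points `i` and `j`.
#'
#' @examples
#' pairwise_distances(data.frame(x = c(0, 3), y = c(0, 4)))
#' @export
pairwise_distances <- function(points) {
  pts <- as_cloud_matrix(points)
  as.matrix(dist(pts))
}

#' Default maximum filtration scale for a point cloud
#'
#' The maximum scale `maxsc` up to which a Vietoris-Rips filtration is grown
#' is taken as half of the maximum pairwise Euclidean distance in the cloud.
#' At that scale (radius convention) the two farthest points become connected,
#' so every connected-component feature of the cloud has died or been capped.
#'
#' @inheritParams pairwise_distances
#'
#' @return A single non-negative number. A cloud whose points all coincide
#'   yields 0 with a warning, since no positive scale is informative there.
#'
#' @examples
#' choose_maxscale(data.frame(x = c(0, 0), y = c(0, 4))) # 2
#' @export
choose_maxscale <- function(points) {
  dm <- pairwise_distances(points)
  m <- max(dm) / 2
  if (m == 0) warn("degenerate point cloud: all points identical, maxscale is 0")
  m
}

# Validate a user-supplied distance matrix.
check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop_invalid("distance matrix must be square")
  }
  if (any(!is.finite(dm)) || any(dm < 0)) {
    stop_invalid("distance matrix entries must be finite and non-negative")
  }
  if (any(abs(dm - t(dm)) > 1e-12) || any(diag(dm) != 0)) {
    stop_invalid("distance matrix must be symmetric with zero diagonal")
  }
  dm
}
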