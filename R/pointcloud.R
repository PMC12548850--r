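# Point-cloud container and preprocessing: multi-frame accumulation, voxel
# downsampling, statistical (kNN) outlier removal, world-scale transform.

#' Point cloud container
#'
#' @param points N x 3 matrix of XYZ coordinates in meters (finite).
#' @param colors optional N x 3 matrix of 8-bit RGB values (0-255).
#' @return object of class `point_cloud` with elements `points` and `colors`.
#' @export
point_cloud <- function(points, colors = NULL) {
  points <- as_points_matrix(points)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == nrow(points), ncol(colors) == 3)
    storage.mode(colors) <- "integer"
  }
  structure(list(points = points, colors = colors), class = "point_cloud")
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an N x 3 matrix")
  storage.mode(points) <- "double"
  if (nrow(points) > 0 && !all(is.finite(points))) {
    stop("point coordinates must be finite")
  }
  dimnames(points) <- NULL
  points
}

as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) x else point_cloud(x)
}

#' @export
format.point_cloud <- function(x, ...) {
  sprintf("<point_cloud %d points%s>", nrow(x$points),
          if (is.null(x$colors)) "" else ", RGB")
}

#' @export
print.point_cloud <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(as_point_cloud(cloud)$points)

#' Accumulate multiple near-simultaneous frames into one cloud
#'
#' Concatenates the frames' points; points that coincide exactly (bitwise
#' coordinate equality) across frames are retained as a single point. Near
#' duplicates are left to voxel downsampling.
#'
#' @param frames non-empty list of [point_cloud()] objects.
#' @return a single accumulated [point_cloud()].
#' @export
accumulate_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of point clouds")
  }
  frames <- lapply(frames, as_point_cloud)
  pts <- do.call(rbind, lapply(frames, `[[`, "points"))
  cols <- lapply(frames, `[[`, "colors")
  have_cols <- !vapply(cols, is.null, logical(1))
  colors <- if (all(have_cols)) do.call(rbind, cols) else NULL
  keep <- !duplicated(pts)
  point_cloud(pts[keep, , drop = FALSE],
              if (is.null(colors)) NULL else colors[keep, , drop = FALSE])
}

#' Voxel downsampling
#'
#' Discretizes space into an axis-aligned grid of cubic voxels of edge
#' `voxel_size` anchored at the origin (voxel index = floor(coord / size) per
#' axis) and keeps the first point, in input order, of each occupied voxel.
#'
#' @param cloud a [point_cloud()].
#' @param voxel_size voxel edge length in meters (> 0); default 0.005.
#' @return downsampled [point_cloud()].
#' @export
voxel_downsample <- function(cloud, voxel_size = 0.005) {
  cloud <- as_point_cloud(cloud)
  stopifnot_scalar_number(voxel_size)
  if (voxel_size <= 0) stop("`voxel_size` must be positive")
  if (nrow(cloud$points) == 0L) return(cloud)
  idx <- floor(cloud$points / voxel_size)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  keep <- !duplicated(key)
  point_cloud(cloud$points[keep, , drop = FALSE],
              if (is.null(cloud$colors)) NULL else cloud$colors[keep, , drop = FALSE])
}

#' Statistical outlier removal by k-nearest-neighbour distance
#'
#' For each point the mean Euclidean distance d_i to its `k` nearest
#' neighbours (query point excluded) is computed. The threshold is
#' T = mean(d) + sigma_mult * sd(d), with mean and sd taken over all points;
#' points with d_i > T are removed.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbour count (default 30).
#' @param sigma_mult threshold multiplier on the standard deviation
#'   (default 2).
#' @return list with elements `cloud` (filtered [point_cloud()]),
#'   `removed` (integer indices of removed points, 1-based) and
#'   `mean_dist` (the per-point kNN mean distances).
#' @export
remove_outliers <- function(cloud, k = 30, sigma_mult = 2) {
  cloud <- as_point_cloud(cloud)
  stopifnot(k >= 1, sigma_mult > 0)
  n <- nrow(cloud$points)
  if (n <= k) {
    warning("cloud has no more points than `k`; returned unchanged")
    return(list(cloud = cloud, removed = integer(0),
                mean_dist = rep(NA_real_, n)))
  }
  d <- cpp_knn_mean_dist(cloud$points, as.integer(k))
  thr <- mean(d) + sigma_mult * sd(d)
  removed <- which(d > thr)
  keep <- setdiff(seq_len(n), removed)
  list(cloud = point_cloud(cloud$points[keep, , drop = FALSE],
                           if (is.null(cloud$colors)) NULL
                           else cloud$colors[keep, , drop = FALSE]),
       removed = removed, mean_dist = d)
}

#' Rigid + scale transform of a cloud into world coordinates
#'
#' Maps each point to scale * (T %*% c(x, y, z, 1))[1:3].
#'
#' @param cloud a [point_cloud()].
#' @param T 4x4 invertible homogeneous transform (default identity).
#' @param scale positive scalar (e.g. 0.001 converts millimeters to meters).
#' @return transformed [point_cloud()].
#' @export
world_transform <- function(cloud, T = diag(4), scale = 1) {
  cloud <- as_point_cloud(cloud)
  T <- as.matrix(T)
  stopifnot(all(dim(T) == c(4, 4)), scale > 0)
  if (abs(det(T)) < .Machine$double.eps) stop("`T` must be invertible")
  if (nrow(cloud$points) == 0L) return(cloud)
  ph <- cbind(cloud$points, 1)
  out <- scale * (ph %*% t(T))[, 1:3, drop = FALSE]
  point_cloud(out, cloud$colors)
}
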