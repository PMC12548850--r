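# Pinhole camera model: 3D -> 2D projection with mirror flip and offset
# correction, plus alignment verification by painting projected regions onto
# the cloud.

#' Pinhole camera intrinsics
#'
#' Focal lengths and principal point in pixels, plus the raster dimensions.
#' The intrinsic matrix is K = [[fx,0,cx],[0,fy,cy],[0,0,1]].
#'
#' @param fx,fy focal lengths along x and y, pixels (> 0).
#' @param cx,cy principal point column/row, pixels (inside the raster).
#' @param width,height raster dimensions, pixels.
#' @return object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  for (v in list(fx, fy, cx, cy, width, height)) stopifnot_scalar_number(v)
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (width < 1 || height < 1 || width != round(width) || height != round(height)) {
    stop("width and height must be positive integers")
  }
  if (cx < 0 || cx >= width || cy < 0 || cy >= height) {
    stop("principal point must lie inside the raster")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
format.camera_intrinsics <- function(x, ...) {
  sprintf("<camera_intrinsics %dx%d fx=%.2f fy=%.2f cx=%.2f cy=%.2f>",
          x$width, x$height, x$fx, x$fy, x$cx, x$cy)
}

#' @export
print.camera_intrinsics <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Camera extrinsics (4x4 homogeneous rigid transform)
#'
#' @param mat 4x4 matrix; rotation block unitless, translation in meters.
#'   Bottom row must be (0,0,0,1). Defaults to the identity.
#' @return object of class `extrinsics`.
#' @export
extrinsics <- function(mat = diag(4)) {
  mat <- as.matrix(mat)
  stopifnot(all(dim(mat) == c(4, 4)), all(is.finite(mat)))
  if (!isTRUE(all.equal(mat[4, ], c(0, 0, 0, 1)))) {
    stop("bottom row of an extrinsic matrix must be (0, 0, 0, 1)")
  }
  structure(list(mat = mat), class = "extrinsics")
}

#' Projection offset correction parameters
#'
#' Per-dataset calibration constants added to the mirrored pixel coordinates.
#'
#' @param xoffset,yoffset column/row corrections in pixels; default (0, 0).
#' @return object of class `projection_offsets`.
#' @export
projection_offsets <- function(xoffset = 0, yoffset = 0) {
  stopifnot_scalar_number(xoffset); stopifnot_scalar_number(yoffset)
  structure(list(xoffset = xoffset, yoffset = yoffset),
            class = "projection_offsets")
}

#' Transform points into the camera frame
#'
#' Applies the extrinsic transform to homogeneous point coordinates and
#' returns the first three components.
#'
#' @param points N x 3 matrix of XYZ coordinates in meters.
#' @param E an [extrinsics()] object (default identity).
#' @return N x 3 matrix of camera-frame coordinates.
#' @export
to_camera <- function(points, E = extrinsics()) {
  points <- as_points_matrix(points)
  stopifnot(inherits(E, "extrinsics"))
  if (nrow(points) == 0L) return(points)
  ph <- cbind(points, 1)
  out <- ph %*% t(E$mat)
  out[, 1:3, drop = FALSE]
}

#' Project camera-frame points onto the image plane
#'
#' Pinhole projection u = x*fx/z + cx, v = y*fy/z + cy. All input points must
#' lie strictly in front of the camera (z > 0).
#'
#' @param p_cam N x 3 matrix of camera-frame coordinates, meters.
#' @param K a [camera_intrinsics()] object.
#' @return N x 2 matrix of continuous (u, v) pixel coordinates.
#' @export
project_points <- function(p_cam, K) {
  p_cam <- as_points_matrix(p_cam)
  stopifnot(inherits(K, "camera_intrinsics"))
  if (any(p_cam[, 3] <= 0)) {
    stop("cannot project points behind the camera (z <= 0)")
  }
  cbind(u = p_cam[, 1] * K$fx / p_cam[, 3] + K$cx,
        v = p_cam[, 2] * K$fy / p_cam[, 3] + K$cy)
}

#' Back-project pixels to camera-frame points at given depth
#'
#' Algebraic inverse of [project_points()]: x = z*(u - cx)/fx,
#' y = z*(v - cy)/fy.
#'
#' @param u,v continuous pixel coordinates (0-based).
#' @param z depth along the optical axis, meters (> 0).
#' @param K a [camera_intrinsics()] object.
#' @return N x 3 matrix of camera-frame coordinates.
#' @export
backproject_pixels <- function(u, v, z, K) {
  stopifnot(inherits(K, "camera_intrinsics"), all(z > 0))
  cbind(x = z * (u - K$cx) / K$fx, y = z * (v - K$cy) / K$fy, z = z)
}

#' Mirror-flip a column coordinate
#'
#' u' = mw - 1 - u. An involution; applied to the column coordinate only.
#'
#' @param u column coordinate(s), pixels.
#' @param mw image width, pixels (>= 1).
#' @return flipped column coordinate(s).
#' @export
mirror_u <- function(u, mw) {
  stopifnot(mw >= 1)
  mw - 1 - u
}

#' Apply projection offset correction
#'
#' @param u_prime mirrored column coordinate(s), pixels.
#' @param v row coordinate(s), pixels.
#' @param off a [projection_offsets()] object.
#' @return matrix with columns `u`, `v`: (u' + xoffset, v + yoffset).
#' @export
offset_correct <- function(u_prime, v, off = projection_offsets()) {
  stopifnot(inherits(off, "projection_offsets"))
  cbind(u = u_prime + off$xoffset, v = v + off$yoffset)
}

#' Project a point cloud onto the image raster
#'
#' Full projection chain: extrinsic transform, pinhole projection, mirror
#' flip of the column coordinate, offset correction, and rasterization
#' (round half away from zero). Points behind the camera or whose rasterized
#' pixel falls outside the image are dropped and counted.
#'
#' @param cloud a [point_cloud()].
#' @param K a [camera_intrinsics()].
#' @param E an [extrinsics()] (default identity).
#' @param off a [projection_offsets()] (default zero).
#' @return data.frame with one row per retained point: `index` (1-based index
#'   into the cloud), continuous corrected coordinates `u`, `v`, rasterized
#'   0-based `col`, `row`, and camera-frame depth `z`. Attributes
#'   `n_behind` and `n_outside` count dropped points.
#' @export
project_cloud <- function(cloud, K, E = extrinsics(), off = projection_offsets()) {
  cloud <- as_point_cloud(cloud)
  stopifnot(inherits(K, "camera_intrinsics"))
  n <- nrow(cloud$points)
  empty <- data.frame(index = integer(0), u = numeric(0), v = numeric(0),
                      col = integer(0), row = integer(0), z = numeric(0))
  if (n == 0L) {
    warning("projecting an empty point cloud")
    attr(empty, "n_behind") <- 0L; attr(empty, "n_outside") <- 0L
    return(empty)
  }
  pc <- to_camera(cloud$points, E)
  front <- pc[, 3] > 0
  n_behind <- sum(!front)
  idx <- which(front)
  if (length(idx) == 0L) {
    attr(empty, "n_behind") <- n_behind; attr(empty, "n_outside") <- 0L
    return(empty)
  }
  uv <- project_points(pc[idx, , drop = FALSE], K)
  uv2 <- offset_correct(mirror_u(uv[, 1], K$width), uv[, 2], off)
  col <- round_half_away(uv2[, 1])
  row <- round_half_away(uv2[, 2])
  inside <- col >= 0 & col <= K$width - 1 & row >= 0 & row <= K$height - 1
  out <- data.frame(index = idx[inside],
                    u = uv2[inside, 1], v = uv2[inside, 2],
                    col = as.integer(col[inside]), row = as.integer(row[inside]),
                    z = pc[idx[inside], 3])
  attr(out, "n_behind") <- n_behind
  attr(out, "n_outside") <- as.integer(sum(!inside))
  out
}

#' Mark cloud points projecting into 2D boxes
#'
#' Alignment verification: points whose corrected projection falls inside any
#' of the given pixel-space rectangles are painted black; all other points
#' (and all coordinates) are unchanged. Clouds without colors are assigned
#' white before marking.
#'
#' @param cloud a [point_cloud()].
#' @param boxes data.frame of rectangles with `xmin`, `ymin`, `xmax`, `ymax`
#'   in pixel coordinates (may be empty).
#' @inheritParams project_cloud
#' @return the cloud with per-point colors; marked points are (0, 0, 0).
#' @export
mark_points_in_boxes <- function(cloud, boxes, K, E = extrinsics(),
                                 off = projection_offsets()) {
  cloud <- as_point_cloud(cloud)
  boxes <- as_box_df(boxes)
  if (is.null(cloud$colors)) {
    cloud$colors <- matrix(255L, nrow = nrow(cloud$points), ncol = 3)
  }
  if (nrow(boxes) == 0L) return(cloud)
  pr <- project_cloud(cloud, K, E, off)
  if (nrow(pr) == 0L) return(cloud)
  hit <- rep(FALSE, nrow(pr))
  for (b in seq_len(nrow(boxes))) {
    hit <- hit | (pr$u >= boxes$xmin[b] & pr$u <= boxes$xmax[b] &
                  pr$v >= boxes$ymin[b] & pr$v <= boxes$ymax[b])
  }
  cloud$colors[pr$index[hit], ] <- 0L
  cloud
}

#' Read camera calibration from a YAML or JSON config block
#'
#' Expected fields: `fx`, `fy`, `cx`, `cy`, `width`, `height`, and optionally
#' `xoffset`, `yoffset` and `extrinsics` (16 row-major numbers).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `K` ([camera_intrinsics()]),
#'   `E` ([extrinsics()]) and `off` ([projection_offsets()]).
#' @export
read_calibration <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  calibration_from_list(cfg)
}

calibration_from_list <- function(cfg) {
  K <- camera_intrinsics(cfg$fx, cfg$fy, cfg$cx, cfg$cy, cfg$width, cfg$height)
  E <- if (!is.null(cfg$extrinsics)) {
    extrinsics(matrix(as.numeric(cfg$extrinsics), 4, 4, byrow = TRUE))
  } else extrinsics()
  off <- projection_offsets(cfg$xoffset %||% 0, cfg$yoffset %||% 0)
  list(K = K, E = E, off = off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
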