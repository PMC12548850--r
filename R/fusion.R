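# Rasterization of depth/XYZ bands and composition of the 8-channel image
# [R, G, B, F, D, X, Y, Z], plus lossless container I/O and raster file I/O.

MCI_BANDS <- c("R", "G", "B", "F", "D", "X", "Y", "Z")

#' Decode a Z16 depth raster to meters
#'
#' Z16 stores one 16-bit unsigned millimeter value per pixel; 0 means
#' no-data. Values decoding above the sensor's 4 m valid range (or equal to
#' zero) are set to 0 (invalid).
#'
#' @param z16 H x W matrix of integer-valued millimeter counts in
#'   \[0, 65535\].
#' @param max_range valid range ceiling in meters (default 4).
#' @return H x W numeric matrix of depths in meters, 0 where invalid.
#' @export
decode_depth <- function(z16, max_range = 4) {
  if (!is.matrix(z16)) stop("`z16` must be a single-band matrix")
  if (any(z16 != round(z16)) || any(z16 < 0) || any(z16 > 65535)) {
    stop("`z16` must hold 16-bit unsigned integer values")
  }
  d <- z16 / 1000
  d[d > max_range | z16 == 0] <- 0
  d
}

#' Encode a meters depth map as Z16 millimeter counts
#'
#' @param depth H x W numeric matrix in meters (0 = no data).
#' @return H x W integer matrix of millimeter counts.
#' @export
encode_depth <- function(depth) {
  m <- round_half_away(depth * 1000)
  m[m < 0] <- 0
  m[m > 65535] <- 0
  storage.mode(m) <- "integer"
  m
}

#' Rasterize a point cloud into X, Y, Z bands
#'
#' Projects every cloud point through the full camera chain and stores the
#' point's (x, y, z) world coordinates at the hit pixel. When several points
#' land on one pixel the nearest (smallest camera depth) wins, which is the
#' occlusion-correct choice. Unsampled pixels hold (0, 0, 0).
#'
#' @param cloud a [point_cloud()].
#' @inheritParams project_cloud
#' @param shape integer c(H, W); defaults to the intrinsics raster size.
#' @return H x W x 3 array with bands X, Y, Z (meters). Attribute
#'   `n_zero_filled` counts unsampled pixels.
#' @export
xyz_raster <- function(cloud, K, E = extrinsics(), off = projection_offsets(),
                       shape = c(K$height, K$width)) {
  cloud <- as_point_cloud(cloud)
  H <- shape[1]; W <- shape[2]
  out <- array(0, dim = c(H, W, 3), dimnames = list(NULL, NULL, c("X", "Y", "Z")))
  if (nrow(cloud$points) == 0L) {
    warning("rasterizing an empty point cloud; all-zero XYZ bands")
    attr(out, "n_zero_filled") <- H * W
    return(out)
  }
  pr <- project_cloud(cloud, K, E, off)
  if (nrow(pr) > 0L) {
    # write in decreasing depth order so the nearest point lands last
    ord <- order(pr$z, decreasing = TRUE)
    lin <- pr$row[ord] + 1L + H * pr$col[ord]
    pts <- cloud$points[pr$index[ord], , drop = FALSE]
    for (b in 1:3) {
      plane <- out[, , b]
      plane[lin] <- pts[, b]
      out[, , b] <- plane
    }
  }
  zplane <- out[, , 3]
  attr(out, "n_zero_filled") <- sum(zplane == 0)
  out
}

#' Compose the 8-channel multimodal image
#'
#' Stacks the bands in the fixed order \[R, G, B, F, D, X, Y, Z\]. RGB input
#' on the 8-bit scale is rescaled to \[0, 1\]; F is already in \[0, 1\];
#' D and XYZ stay in raw meters (zero where unsampled).
#'
#' @param rgb H x W x 3 array, 8-bit scale (0-255).
#' @param f H x W key-feature matrix in \[0, 1\].
#' @param d H x W depth matrix in meters.
#' @param xyz H x W x 3 array of per-pixel point coordinates, meters.
#' @return object of class `multichannel_image`: an H x W x 8 array with
#'   named bands.
#' @export
compose <- function(rgb, f, d, xyz) {
  if (missing(rgb) || is.null(rgb)) stop("band RGB is missing")
  if (missing(f) || is.null(f)) stop("band F is missing")
  if (missing(d) || is.null(d)) stop("band D is missing")
  if (missing(xyz) || is.null(xyz)) stop("band XYZ is missing")
  check_rgb_raster(rgb)
  hw <- dim(rgb)[1:2]
  for (nm in c("f", "d")) {
    b <- get(nm)
    if (!is.matrix(b) || !all(dim(b) == hw)) {
      stop(sprintf("band %s does not match the RGB shape", toupper(nm)))
    }
  }
  if (!is.array(xyz) || length(dim(xyz)) != 3L || dim(xyz)[3] != 3L ||
      !all(dim(xyz)[1:2] == hw)) {
    stop("band XYZ does not match the RGB shape")
  }
  out <- array(0, dim = c(hw, 8), dimnames = list(NULL, NULL, MCI_BANDS))
  out[, , 1:3] <- rgb / 255
  out[, , 4] <- f
  out[, , 5] <- d
  out[, , 6:8] <- xyz
  if (!all(is.finite(out))) stop("composed image contains non-finite values")
  structure(out, class = c("multichannel_image", "array"))
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<multichannel_image %d x %d, bands [%s]>\n", d[1], d[2],
              paste(dimnames(x)[[3]], collapse = ",")))
  invisible(x)
}

#' Write a multi-channel image container
#'
#' One little-endian float64 binary array file plus a JSON sidecar carrying
#' the shape, band names and optional provenance metadata (calibration,
#' preprocessing parameters). The round trip is lossless.
#'
#' @param img a `multichannel_image` (or any named-band H x W x C array).
#' @param path output path for the binary array; the sidecar is
#'   `paste0(path, ".json")`.
#' @param metadata optional list of provenance values stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_container <- function(img, path, metadata = list()) {
  stopifnot(is.array(img), length(dim(img)) == 3L)
  bands <- dimnames(img)[[3]]
  if (is.null(bands)) stop("container images must have named bands")
  sidecar <- list(shape = dim(img), bands = bands, dtype = "float64",
                  byte_order = "little", metadata = metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(img), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a multi-channel image container
#'
#' @param path path written by [write_container()].
#' @param expect_bands optional character vector; error if the stored bands
#'   differ.
#' @return a `multichannel_image` with attribute `metadata`.
#' @export
read_container <- function(path, expect_bands = NULL) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop("missing container sidecar: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$shape) || is.null(sc$bands) ||
      length(sc$shape) != 3L || length(sc$bands) != sc$shape[3]) {
    stop("corrupt container sidecar (shape/band metadata)")
  }
  if (!is.null(expect_bands) && !identical(as.character(sc$bands),
                                           as.character(expect_bands))) {
    stop(sprintf("container bands [%s] do not match expected [%s]",
                 paste(sc$bands, collapse = ","),
                 paste(expect_bands, collapse = ",")))
  }
  n <- prod(sc$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(vals) != n) stop("container payload shorter than its shape")
  img <- array(vals, dim = sc$shape,
               dimnames = list(NULL, NULL, as.character(sc$bands)))
  attr(img, "metadata") <- sc$metadata
  class(img) <- c("multichannel_image", "array")
  img
}

#' Read an 8-bit RGB image (PNG)
#'
#' @param path path to an 8-bit RGB PNG.
#' @return H x W x 3 numeric array on the 0-255 scale.
#' @export
read_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) stop("expected a 3-band image")
  img[, , 1:3, drop = FALSE] * 255
}

#' Write an 8-bit RGB image (PNG)
#'
#' @param rgb H x W x 3 array on the 0-255 scale.
#' @param path output path.
#' @export
write_rgb <- function(rgb, path) {
  check_rgb_raster(rgb)
  png::writePNG(pmin(pmax(rgb / 255, 0), 1), path)
  invisible(path)
}

#' Write a single-band feature map as an 8-bit PNG for inspection
#'
#' @param m H x W matrix in \[0, 1\].
#' @param path output path.
#' @export
write_feature_png <- function(m, path) {
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}

#' Read/write a 16-bit depth raster (TIFF carrier)
#'
#' Depth rasters hold Z16 millimeter counts. The on-disk carrier is a 16-bit
#' grayscale TIFF; [decode_depth()] interprets the integer values.
#'
#' @param path file path.
#' @return for the reader, an H x W integer matrix of millimeter counts.
#' @export
read_depth_raster <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_depth_raster
#' @param z16 H x W integer matrix of millimeter counts in \[0, 65535\].
#' @export
write_depth_raster <- function(z16, path) {
  stopifnot(is.matrix(z16), all(z16 >= 0), all(z16 <= 65535))
  tiff::writeTIFF(z16 / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
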