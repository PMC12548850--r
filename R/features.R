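# Key fruit feature extraction: R-G chroma map, Laplacian edge map,
# min-max normalization, and 6:4 weighted fusion into the F band.

check_rgb_raster <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("expected an H x W x 3 raster")
  }
  invisible(rgb)
}

#' R-G chroma map
#'
#' Per-pixel signed difference R - G computed in double precision, with
#' negative (green-dominant) responses clipped to zero: red fruit carries all
#' the signal of interest, green foliage none.
#'
#' @param rgb H x W x 3 numeric array, 8-bit scale (values 0-255).
#' @return H x W matrix of unnormalized chroma values in \[0, 255\].
#' @export
rg_chroma_map <- function(rgb) {
  check_rgb_raster(rgb)
  pmax(rgb[, , 1] - rgb[, , 2], 0)
}

# 4-neighbour Laplacian; the most common discrete variant.
laplacian_kernel_4 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
# 8-neighbour variant, selectable through the config.
laplacian_kernel_8 <- matrix(c(1, 1, 1, 1, -8, 1, 1, 1, 1), 3, 3)

# 3x3 convolution with replicate (clamp-to-edge) padding, so a constant
# image has an identically zero second derivative everywhere.
conv3x3_replicate <- function(m, kernel) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[H + 2, ] <- pad[H + 1, ]
  pad[, 1] <- pad[, 2]; pad[, W + 2] <- pad[, W + 1]
  out <- matrix(0, H, W)
  for (di in 0:2) {
    for (dj in 0:2) {
      kv <- kernel[di + 1, dj + 1]
      if (kv != 0) {
        out <- out + kv * pad[di + seq_len(H), dj + seq_len(W)]
      }
    }
  }
  out
}

#' Grayscale conversion (ITU-R BT.601 weights)
#'
#' @param rgb H x W x 3 numeric array.
#' @return H x W matrix, 0.299 R + 0.587 G + 0.114 B.
#' @export
to_grayscale <- function(rgb) {
  check_rgb_raster(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Laplacian edge map
#'
#' Converts the image to grayscale (BT.601), convolves with a Laplacian
#' kernel (4-neighbour by default) using replicate padding, and takes the
#' absolute response.
#'
#' @param rgb H x W x 3 numeric array, 8-bit scale.
#' @param kernel `"lap4"` (default) or `"lap8"`.
#' @return H x W matrix of unnormalized nonnegative edge magnitudes.
#' @export
edge_map <- function(rgb, kernel = c("lap4", "lap8")) {
  check_rgb_raster(rgb)
  kernel <- match.arg(kernel)
  k <- if (kernel == "lap4") laplacian_kernel_4 else laplacian_kernel_8
  abs(conv3x3_replicate(to_grayscale(rgb), k))
}

#' Min-max normalization of a feature map
#'
#' Scales values linearly to \[0, 1\]; a constant map (degenerate range) maps
#' to all zeros rather than dividing by zero.
#'
#' @param m H x W numeric matrix with finite values.
#' @return H x W matrix with values in \[0, 1\].
#' @export
normalize_map <- function(m) {
  stopifnot(all(is.finite(m)))
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Key fruit feature map (weighted chroma/edge fusion)
#'
#' F = w_chroma * chroma + w_edge * edge, elementwise, on normalized inputs.
#' The default 6:4 weighting favours the chroma response.
#'
#' @param chroma,edge H x W matrices with values in \[0, 1\] and equal shape.
#' @param w_chroma,w_edge fusion weights; must sum to 1 (default 0.6 / 0.4).
#' @return H x W matrix with values in \[0, 1\].
#' @export
key_feature <- function(chroma, edge, w_chroma = 0.6, w_edge = 0.4) {
  if (!all(dim(chroma) == dim(edge))) {
    stop("`chroma` and `edge` must have the same shape")
  }
  if (abs(w_chroma + w_edge - 1) > 1e-9) {
    stop("fusion weights must sum to 1")
  }
  if (min(chroma) < 0 || max(chroma) > 1 || min(edge) < 0 || max(edge) > 1) {
    stop("inputs must be normalized to [0, 1]")
  }
  w_chroma * chroma + w_edge * edge
}

#' Full key-feature extraction from an RGB image
#'
#' Convenience wrapper: normalized chroma and edge maps plus their fusion.
#'
#' @inheritParams rg_chroma_map
#' @inheritParams key_feature
#' @param kernel Laplacian variant passed to [edge_map()].
#' @return list with matrices `chroma`, `edge` (both normalized) and `F`.
#' @export
extract_features <- function(rgb, w_chroma = 0.6, w_edge = 0.4,
                             kernel = "lap4") {
  chroma <- normalize_map(rg_chroma_map(rgb))
  edge <- normalize_map(edge_map(rgb, kernel))
  list(chroma = chroma, edge = edge,
       F = key_feature(chroma, edge, w_chroma, w_edge))
}
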