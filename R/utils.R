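# Internal helpers shared across modules.

# Round half away from zero (used only at rasterization, never inside the
# projection math).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Axis-aligned boxes as a data.frame with xmin/ymin/xmax/ymax (pixels).
as_box_df <- function(boxes) {
  if (is.null(boxes) || (is.data.frame(boxes) && nrow(boxes) == 0L)) {
    return(data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0)))
  }
  if (is.matrix(boxes)) boxes <- as.data.frame(boxes)
  stopifnot(all(c("xmin", "ymin", "xmax", "ymax") %in% names(boxes)))
  boxes
}

# Pairwise intersection-over-union of two box data.frames.
box_iou <- function(a, b) {
  a <- as_box_df(a); b <- as_box_df(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- ix * iy
  area_a <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
  area_b <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
  uni <- outer(area_a, area_b, `+`) - inter
  out <- inter / pmax(uni, .Machine$double.eps)
  out
}

# YOLO text labels: "class cx cy w h" with coordinates normalized to [0,1].
#' Read YOLO-format box labels
#'
#' @param path path to a YOLO label text file (one `class cx cy w h` row per
#'   box, coordinates normalized by image size).
#' @param width,height image dimensions in pixels used to de-normalize.
#' @return data.frame with columns `class`, `xmin`, `ymin`, `xmax`, `ymax`
#'   (pixels) and `w`, `h`.
#' @export
read_yolo_labels <- function(path, width, height) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(class = integer(0), xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  cx <- m[, 2] * width; cy <- m[, 3] * height
  w <- m[, 4] * width; h <- m[, 5] * height
  data.frame(class = as.integer(m[, 1]),
             xmin = cx - w / 2, ymin = cy - h / 2,
             xmax = cx + w / 2, ymax = cy + h / 2, w = w, h = h)
}

#' Write YOLO-format box labels
#'
#' @param boxes data.frame with `xmin`, `ymin`, `xmax`, `ymax` in pixels and
#'   optionally `class` (default 0).
#' @param path output text file.
#' @param width,height image dimensions in pixels used to normalize.
#' @export
write_yolo_labels <- function(boxes, path, width, height) {
  boxes <- as_box_df(boxes)
  cls <- if ("class" %in% names(boxes)) boxes$class else rep(0L, nrow(boxes))
  cx <- (boxes$xmin + boxes$xmax) / 2 / width
  cy <- (boxes$ymin + boxes$ymax) / 2 / height
  w <- (boxes$xmax - boxes$xmin) / width
  h <- (boxes$ymax - boxes$ymin) / height
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", cls, cx, cy, w, h), path)
  invisible(path)
}
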