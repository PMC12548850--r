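# Minimal PLY reader/writer for XYZ (+ optional 8-bit RGB) vertex clouds.
# Supports ascii and binary_little_endian, float/double coordinates and
# uchar colors, which covers the clouds this pipeline exchanges.

#' Read a PLY point cloud
#'
#' @param path path to a `.ply` file (ascii or binary_little_endian) with a
#'   vertex element carrying `x`, `y`, `z` and optionally `red`, `green`,
#'   `blue` properties.
#' @return a [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- read_line_raw(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 200) stop("PLY header not terminated")
  }
  if (!identical(header[1], "ply")) stop("not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  # parse elements and their properties in order
  elems <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = character(0),
                           types = character(0))
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") stop("list properties are not supported")
      elems[[cur]]$types <- c(elems[[cur]]$types, tok[2])
      elems[[cur]]$props <- c(elems[[cur]]$props, tok[3])
    }
  }
  if (is.null(elems$vertex)) stop("PLY file has no vertex element")
  v <- elems$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% v$props)) stop("vertex element must carry x, y, z")
  nv <- v$count
  np <- length(v$props)
  if (fmt == "ascii") {
    txt <- readLines(con, n = nv)
    m <- matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
                ncol = np, byrow = TRUE)
  } else {
    sizes <- c(char = 1L, uchar = 1L, uint8 = 1L, int8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[v$types]
    if (any(is.na(sz))) stop("unsupported property type in PLY")
    if (length(unique(sz)) == 1L && all(v$types %in% c("float", "float32"))) {
      vals <- readBin(con, "double", n = nv * np, size = 4L, endian = "little")
      m <- matrix(vals, ncol = np, byrow = TRUE)
    } else {
      # mixed record: read the raw block and decode column-wise
      rec <- sum(sz)
      raw <- readBin(con, "raw", n = nv * rec)
      m <- matrix(0, nrow = nv, ncol = np)
      off <- cumsum(c(0L, sz[-np]))
      for (j in seq_len(np)) {
        byte_idx <- outer(seq_len(sz[j]), (seq_len(nv) - 1L) * rec + off[j], `+`)
        col_raw <- raw[as.vector(byte_idx)]
        m[, j] <- decode_ply_column(col_raw, v$types[j], nv)
      }
    }
  }
  colnames(m) <- v$props
  pts <- m[, need, drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% v$props)) {
    colors <- m[, c("red", "green", "blue"), drop = FALSE]
  }
  point_cloud(pts, colors)
}

read_line_raw <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("unexpected end of file in PLY header")
    if (b == as.raw(10L)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

decode_ply_column <- function(col_raw, type, n) {
  switch(type,
    uchar = , uint8 = as.numeric(readBin(col_raw, "integer", n = n, size = 1L,
                                         signed = FALSE, endian = "little")),
    char = , int8 = as.numeric(readBin(col_raw, "integer", n = n, size = 1L,
                                       signed = TRUE, endian = "little")),
    ushort = , uint16 = as.numeric(readBin(col_raw, "integer", n = n, size = 2L,
                                           signed = FALSE, endian = "little")),
    short = , int16 = as.numeric(readBin(col_raw, "integer", n = n, size = 2L,
                                         signed = TRUE, endian = "little")),
    int = , int32 = , uint = , uint32 =
      as.numeric(readBin(col_raw, "integer", n = n, size = 4L, endian = "little")),
    float = , float32 = readBin(col_raw, "double", n = n, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(col_raw, "double", n = n, size = 8L,
                                 endian = "little"),
    stop("unsupported PLY property type: ", type))
}

#' Write a point cloud to PLY
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"binary"` (binary_little_endian, float coordinates) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, format = c("binary", "ascii")) {
  cloud <- as_point_cloud(cloud)
  format <- match.arg(format)
  n <- nrow(cloud$points)
  has_col <- !is.null(cloud$colors)
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (format == "ascii") "ascii" else "binary_little_endian"),
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0L) return(invisible(path))
  if (format == "ascii") {
    if (has_col) {
      writeLines(sprintf("%.9g %.9g %.9g %d %d %d",
                         cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                         cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3]),
                 con, sep = "\n")
    } else {
      writeLines(sprintf("%.9g %.9g %.9g",
                         cloud$points[, 1], cloud$points[, 2], cloud$points[, 3]),
                 con, sep = "\n")
    }
  } else {
    coord_raw <- writeBin(as.numeric(t(cloud$points)), raw(), size = 4L,
                          endian = "little")
    if (!has_col) {
      writeBin(coord_raw, con)
    } else {
      rec <- 15L  # 3 x float32 + 3 x uchar
      out <- raw(n * rec)
      coord_pos <- rep((seq_len(n) - 1L) * rec, each = 12L) + seq_len(12L)
      out[coord_pos] <- coord_raw
      col_pos <- rep((seq_len(n) - 1L) * rec + 12L, each = 3L) + seq_len(3L)
      out[col_pos] <- as.raw(t(cloud$colors))
      writeBin(out, con)
    }
  }
  invisible(path)
}
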