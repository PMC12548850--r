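# Synthetic orchard scenes: red quasi-spherical fruits over green/brown
# clutter, rendered through the same pinhole model the pipeline assumes, so
# RGB, depth raster, point cloud and labels are mutually consistent by
# construction (shared z-buffer).

#' Synthetic scene parameters
#'
#' Defaults describe a close-range orchard capture: a handful of apples
#' (radius 3-5 cm) at 0.4-1.8 m from the camera, leaf/branch clutter, and a
#' per-scene global illumination gain spanning dim to bright light.
#'
#' @param n_fruits number of fruit spheres placed per scene.
#' @param fruit_radius c(min, max) sphere radius in meters.
#' @param depth_range c(min, max) fruit center depth in meters (within the
#'   sensor's 0-4 m envelope).
#' @param illumination c(min, max) per-scene RGB gain range.
#' @param occlusion_prob probability that a fruit receives a dedicated
#'   occluding leaf in front of it.
#' @param clutter_density number of clutter ellipses (leaves/branches).
#' @param seed scene RNG seed; fixes the scene completely.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(n_fruits = 6, fruit_radius = c(0.03, 0.05),
                         depth_range = c(0.4, 1.8),
                         illumination = c(0.4, 1.3),
                         occlusion_prob = 0.3, clutter_density = 25,
                         seed = 0) {
  stopifnot(n_fruits >= 0, all(fruit_radius > 0), all(depth_range > 0.3),
            all(depth_range < 4), all(illumination > 0),
            occlusion_prob >= 0, occlusion_prob <= 1, clutter_density >= 0)
  structure(list(n_fruits = as.integer(n_fruits), fruit_radius = fruit_radius,
                 depth_range = depth_range, illumination = illumination,
                 occlusion_prob = occlusion_prob,
                 clutter_density = as.integer(clutter_density), seed = seed),
            class = "scene_params")
}

#' Default synthetic-capture intrinsics
#'
#' A 848 x 480 pinhole model with square 425 px focal length, optionally
#' downscaled (intrinsics and raster together) for desk-scale experiments.
#'
#' @param scale resolution divisor (1 = full 848 x 480).
#' @return a [camera_intrinsics()].
#' @export
default_intrinsics <- function(scale = 1) {
  camera_intrinsics(fx = 425 / scale, fy = 425 / scale,
                    cx = 424 / scale, cy = 240 / scale,
                    width = round(848 / scale), height = round(480 / scale))
}

# Invert the raster chain (offsets then mirror) back to pinhole coordinates.
raster_to_pinhole_u <- function(uo, K, off) mirror_u(uo - off$xoffset, K$width)
raster_to_pinhole_v <- function(vo, K, off) vo - off$yoffset

#' Generate one synthetic orchard scene
#'
#' Renders fruit spheres and clutter ellipses into a shared z-buffer through
#' the full camera chain (pinhole projection, mirror flip, offsets), then
#' derives the color image (with per-scene illumination gain), the Z16 depth
#' raster, the colored point cloud (by back-projecting every valid pixel)
#' and YOLO-style labels. Fruits whose occluded area exceeds 80% of their
#' total projected area are omitted from the labels.
#'
#' @param params a [scene_params()].
#' @param K a [camera_intrinsics()].
#' @param off a [projection_offsets()] (default zero).
#' @return list with `rgb` (H x W x 3, 0-255), `depth_raw` (H x W integer
#'   millimeter counts), `cloud` ([point_cloud()] with colors), `labels`
#'   (data.frame xmin/ymin/xmax/ymax/class), `fruits` (per-fruit geometry
#'   and visible fraction) and `gain` (the illumination gain used).
#' @export
generate_scene <- function(params, K = default_intrinsics(4),
                           off = projection_offsets()) {
  stopifnot(inherits(params, "scene_params"), inherits(K, "camera_intrinsics"))
  with_seed(params$seed, {
    H <- K$height; W <- K$width
    gain <- runif(1, params$illumination[1], params$illumination[2])

    zbuf <- matrix(Inf, H, W)
    owner <- matrix(0L, H, W)   # 0 background, -1 clutter, i > 0 fruit i
    col_r <- matrix(0, H, W); col_g <- matrix(0, H, W); col_b <- matrix(0, H, W)

    # background wall: blocky green/brown mottle at 3.2-3.9 m
    z_bg <- runif(1, 3.2, 3.9)
    block <- 8L
    bh <- ceiling(H / block); bw <- ceiling(W / block)
    mix <- matrix(runif(bh * bw), bh, bw)
    mixful <- mix[rep(seq_len(bh), each = block)[1:H],
                  rep(seq_len(bw), each = block)[1:W]]
    col_r[] <- 60 + 60 * mixful; col_g[] <- 80 + 40 * mixful
    col_b[] <- 35 + 25 * mixful
    zbuf[] <- z_bg

    draw_ellipse <- function(u0, v0, a, b, theta, z, rgbcol) {
      ur <- ceiling(max(a, b))
      us <- max(0, floor(u0 - ur)):min(W - 1, ceiling(u0 + ur))
      vs <- max(0, floor(v0 - ur)):min(H - 1, ceiling(v0 + ur))
      if (length(us) == 0 || length(vs) == 0) return(invisible())
      uu <- outer(rep(1, length(vs)), us); vv <- outer(vs, rep(1, length(us)))
      du <- uu - u0; dv <- vv - v0
      xr <- du * cos(theta) + dv * sin(theta)
      yr <- -du * sin(theta) + dv * cos(theta)
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      rows <- vv + 1L; cols <- uu + 1L
      lin <- cbind(rows[inside], cols[inside])
      if (nrow(lin) == 0) return(invisible())
      zli <- z + 0.002 * xr[inside] / a  # slight tilt so depth is not flat
      upd <- zli < zbuf[lin]
      lin <- lin[upd, , drop = FALSE]
      if (nrow(lin) == 0) return(invisible())
      zbuf[lin] <<- zli[upd]
      owner[lin] <<- -1L
      shade <- 0.8 + 0.4 * runif(nrow(lin))
      col_r[lin] <<- pmin(rgbcol[1] * shade, 255)
      col_g[lin] <<- pmin(rgbcol[2] * shade, 255)
      col_b[lin] <<- pmin(rgbcol[3] * shade, 255)
      invisible()
    }

    # clutter: leaves (green ellipses) and branches (elongated brown)
    for (i in seq_len(params$clutter_density)) {
      is_branch <- runif(1) < 0.3
      zc <- runif(1, params$depth_range[1], 3.0)
      scale_px <- K$fx / zc
      if (is_branch) {
        a <- runif(1, 0.08, 0.25) * scale_px; b <- runif(1, 0.004, 0.01) * scale_px
        colr <- c(100, 70, 40) * runif(1, 0.7, 1.1)
      } else {
        a <- runif(1, 0.02, 0.05) * scale_px; b <- a * runif(1, 0.4, 0.8)
        colr <- c(50, 120, 45) * runif(1, 0.7, 1.2)
      }
      draw_ellipse(runif(1, 0, W - 1), runif(1, 0, H - 1), max(a, 1),
                   max(b, 0.5), runif(1, 0, pi), zc, colr)
    }

    # fruits: ray-traced spheres through the inverse raster chain
    fruits <- vector("list", params$n_fruits)
    render_fruit <- function(id, u0, v0, z0, r) {
      # sphere center along the pixel ray at depth z0
      up <- raster_to_pinhole_u(u0, K, off)
      vp <- raster_to_pinhole_v(v0, K, off)
      cxyz <- c(z0 * (up - K$cx) / K$fx, z0 * (vp - K$cy) / K$fy, z0)
      pr_rad <- r * K$fx / z0 + 2
      us <- max(0, floor(u0 - pr_rad)):min(W - 1, ceiling(u0 + pr_rad))
      vs <- max(0, floor(v0 - pr_rad)):min(H - 1, ceiling(v0 + pr_rad))
      if (length(us) == 0 || length(vs) == 0) {
        return(list(full = matrix(NA, 0, 2)))
      }
      uu <- outer(rep(1, length(vs)), us); vv <- outer(vs, rep(1, length(us)))
      up_g <- raster_to_pinhole_u(uu, K, off)
      vp_g <- raster_to_pinhole_v(vv, K, off)
      dx <- (up_g - K$cx) / K$fx; dy <- (vp_g - K$cy) / K$fy
      # ray p = t * (dx, dy, 1); nearest intersection with the sphere
      A <- dx^2 + dy^2 + 1
      Bc <- -2 * (dx * cxyz[1] + dy * cxyz[2] + cxyz[3])
      Cc <- sum(cxyz^2) - r^2
      disc <- Bc^2 - 4 * A * Cc
      hit <- disc >= 0
      if (!any(hit)) return(list(full = matrix(NA, 0, 2)))
      t_near <- (-Bc[hit] - sqrt(disc[hit])) / (2 * A[hit])
      rows <- vv[hit] + 1L; cols <- uu[hit] + 1L
      lin <- cbind(rows, cols)
      # shading from the surface normal's z component (headlight model)
      px <- t_near * dx[hit]; py <- t_near * dy[hit]; pz <- t_near
      nz <- -(pz - cxyz[3]) / r
      shade <- 0.45 + 0.55 * pmax(nz, 0)
      tint <- runif(3, 0.9, 1.1)
      upd <- t_near < zbuf[lin] & t_near > 0
      lin_u <- lin[upd, , drop = FALSE]
      if (nrow(lin_u) > 0) {
        zbuf[lin_u] <<- t_near[upd]
        owner[lin_u] <<- id
        col_r[lin_u] <<- pmin(205 * tint[1] * shade[upd], 255)
        col_g[lin_u] <<- pmin(45 * tint[2] * shade[upd], 255)
        col_b[lin_u] <<- pmin(50 * tint[3] * shade[upd], 255)
      }
      list(full = lin, center = cxyz, radius = r, u0 = u0, v0 = v0)
    }

    for (i in seq_len(params$n_fruits)) {
      z0 <- runif(1, params$depth_range[1], params$depth_range[2])
      r <- runif(1, params$fruit_radius[1], params$fruit_radius[2])
      pr <- r * K$fx / z0
      u0 <- runif(1, pr * 0.2, W - 1 - pr * 0.2)
      v0 <- runif(1, pr * 0.2, H - 1 - pr * 0.2)
      fruits[[i]] <- render_fruit(i, u0, v0, z0, r)
      if (runif(1) < params$occlusion_prob && nrow(fruits[[i]]$full) > 0) {
        ang <- runif(1, 0, 2 * pi)
        draw_ellipse(u0 + 0.8 * pr * cos(ang), v0 + 0.8 * pr * sin(ang),
                     max(pr * runif(1, 0.6, 1.1), 1),
                     max(pr * runif(1, 0.5, 0.9), 1),
                     runif(1, 0, pi), max(z0 - r - 0.05, 0.31),
                     c(50, 120, 45) * runif(1, 0.8, 1.1))
      }
    }

    # labels: visible fraction from z-buffer ownership; boxes from the full
    # (unoccluded, image-clipped) projection, as an annotator would box them
    labels <- list()
    fruit_info <- list()
    for (i in seq_len(params$n_fruits)) {
      fr <- fruits[[i]]
      a_full <- nrow(fr$full)
      if (a_full == 0) next
      a_vis <- sum(owner[fr$full] == i)
      vis_frac <- a_vis / a_full
      fruit_info[[length(fruit_info) + 1]] <-
        data.frame(fruit = i, cx = fr$center[1], cy = fr$center[2],
                   cz = fr$center[3], radius = fr$radius,
                   u0 = fr$u0, v0 = fr$v0, visible_fraction = vis_frac)
      if (vis_frac >= 0.2) {  # occluded area <= 80% of total
        cols <- fr$full[, 2] - 1L; rows <- fr$full[, 1] - 1L
        labels[[length(labels) + 1]] <-
          data.frame(xmin = min(cols), ymin = min(rows),
                     xmax = max(cols) + 1, ymax = max(rows) + 1, class = 0L)
      }
    }
    labels <- if (length(labels)) do.call(rbind, labels) else
      data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
                 ymax = numeric(0), class = integer(0))
    fruit_info <- if (length(fruit_info)) do.call(rbind, fruit_info) else
      data.frame(fruit = integer(0), cx = numeric(0), cy = numeric(0),
                 cz = numeric(0), radius = numeric(0), u0 = numeric(0),
                 v0 = numeric(0), visible_fraction = numeric(0))

    rgb <- array(0, dim = c(H, W, 3))
    rgb[, , 1] <- pmin(col_r * gain, 255)
    rgb[, , 2] <- pmin(col_g * gain, 255)
    rgb[, , 3] <- pmin(col_b * gain, 255)

    depth_m <- zbuf
    depth_m[!is.finite(depth_m) | depth_m > 4] <- 0
    depth_raw <- encode_depth(depth_m)

    # cloud: back-project every valid pixel through the inverse chain
    valid <- which(depth_m > 0)
    rows <- ((valid - 1L) %% H)
    cols <- ((valid - 1L) %/% H)
    up <- raster_to_pinhole_u(cols, K, off)
    vp <- raster_to_pinhole_v(rows, K, off)
    z <- depth_m[valid]
    pts <- cbind(z * (up - K$cx) / K$fx, z * (vp - K$cy) / K$fy, z)
    colors <- cbind(rgb[, , 1][valid], rgb[, , 2][valid], rgb[, , 3][valid])
    cloud <- point_cloud(pts, round(colors))

    list(rgb = rgb, depth_raw = depth_raw, cloud = cloud, labels = labels,
         fruits = fruit_info, gain = gain, K = K, off = off)
  })
}

#' Inject synthetic noise into a point cloud
#'
#' Adds `n_outliers` far points (displaced from random cloud points by
#' `displacement` in a random direction) and Gaussian coordinate jitter to
#' the original points. Intended as a test fixture for the denoising stage.
#'
#' @param cloud a [point_cloud()].
#' @param n_outliers number of far points to append.
#' @param displacement outlier displacement in meters (should exceed the
#'   typical neighbour spacing by a wide margin).
#' @param jitter_sigma Gaussian jitter SD in meters applied to the original
#'   points (0 disables).
#' @param seed RNG seed.
#' @return list with `cloud` (noisy [point_cloud()]) and `outlier_indices`
#'   (1-based positions of the injected points in the new cloud).
#' @export
inject_cloud_noise <- function(cloud, n_outliers, displacement = 1,
                               jitter_sigma = 0, seed = 0) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud$points)
  with_seed(seed, {
    pts <- cloud$points
    if (jitter_sigma > 0 && n > 0) {
      pts <- pts + matrix(rnorm(3 * n, 0, jitter_sigma), n, 3)
    }
    out_idx <- integer(0)
    if (n_outliers > 0) {
      base <- pts[sample.int(n, n_outliers, replace = TRUE), , drop = FALSE]
      dir <- matrix(rnorm(3 * n_outliers), n_outliers, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      outs <- base + dir * displacement
      pts <- rbind(pts, outs)
      out_idx <- n + seq_len(n_outliers)
    }
    colors <- cloud$colors
    if (!is.null(colors) && n_outliers > 0) {
      colors <- rbind(colors, matrix(255L, n_outliers, 3))
    }
    list(cloud = point_cloud(pts, colors), outlier_indices = out_idx)
  })
}

#' Generate a split synthetic dataset
#'
#' Generates `n_scenes` scenes with per-scene seeds derived from `seed`,
#' shuffles them and assigns 70/10/20 train/validation/test membership (or
#' the given proportions).
#'
#' @param n_scenes number of scenes.
#' @param params a [scene_params()] template (its seed field is replaced per
#'   scene).
#' @param K a [camera_intrinsics()].
#' @param split proportions c(train, val, test) summing to 1.
#' @param seed RNG seed driving scene seeds and the shuffle.
#' @param out_dir optional directory; when given, each scene's RGB (PNG),
#'   depth raster (16-bit TIFF), cloud (PLY) and YOLO labels are written
#'   along with a JSON manifest.
#' @return list with `scenes` (list of [generate_scene()] outputs) and
#'   `manifest` (data.frame scene/seed/split).
#' @export
make_dataset <- function(n_scenes, params = scene_params(),
                         K = default_intrinsics(4),
                         split = c(0.7, 0.1, 0.2), seed = 0, out_dir = NULL) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3)
  n_train <- round(split[1] * n_scenes)
  n_val <- round(split[2] * n_scenes)
  n_test <- n_scenes - n_train - n_val
  if (n_train < 1 || n_test < 1 || (split[2] > 0 && n_val < 1)) {
    stop("`n_scenes` too small for the requested split")
  }
  scene_seeds <- seed * 10000L + seq_len(n_scenes)
  scenes <- lapply(scene_seeds, function(s) {
    p <- params; p$seed <- s
    generate_scene(p, K)
  })
  ord <- with_seed(seed, sample.int(n_scenes))
  membership <- character(n_scenes)
  membership[ord[seq_len(n_train)]] <- "train"
  if (n_val > 0) membership[ord[n_train + seq_len(n_val)]] <- "val"
  membership[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  manifest <- data.frame(scene = seq_len(n_scenes), seed = scene_seeds,
                         split = membership)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_scenes)) {
      base <- file.path(out_dir, sprintf("scene_%04d", i))
      write_rgb(scenes[[i]]$rgb, paste0(base, ".png"))
      write_depth_raster(scenes[[i]]$depth_raw, paste0(base, "_depth.tif"))
      write_ply(scenes[[i]]$cloud, paste0(base, ".ply"))
      write_yolo_labels(scenes[[i]]$labels, paste0(base, ".txt"),
                        K$width, K$height)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scenes = scenes, manifest = manifest)
}
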