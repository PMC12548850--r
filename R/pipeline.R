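# End-to-end orchestration: configuration, channel selection, scene
# preprocessing to multi-channel stacks, and the channel-configuration
# comparison experiment.

#' Pipeline configuration
#'
#' Single configuration object driving every stage; all defaults are the
#' pipeline's canonical values: 6:4 feature fusion weights, k = 30
#' neighbours with a mean + 2 sigma outlier threshold, 5 mm voxels, 30
#' k-means iterations, ratio threshold 4 and BPR cutoff 0.98, and the SGD
#' settings of [train_config()].
#'
#' @param channels character vector of channel configurations to run, e.g.
#'   `c("RGB", "RGB+XYZ+D+F")`; tokens RGB, R-G, E, F, D, XYZ.
#' @param voxel_size voxel edge in meters for downsampling.
#' @param outlier_k,outlier_sigma kNN outlier-removal parameters.
#' @param denoise apply outlier removal during preprocessing.
#' @param w_chroma,w_edge key-feature fusion weights (sum to 1).
#' @param edge_kernel Laplacian variant, `"lap4"` or `"lap8"`.
#' @param d_max depth normalization ceiling in meters (training view).
#' @param xy_half fixed scene half-extents in meters normalizing the X and Y
#'   bands (training view).
#' @param anchor_k anchors to estimate when the defaults fail the BPR gate.
#' @param ratio_threshold,bpr_cutoff anchor adequacy parameters.
#' @param kmeans_iters,ga_generations,ga_mut_prob,ga_sigma anchor
#'   re-estimation parameters.
#' @param epochs training epochs per run (desk-scale; `max_epochs` of the
#'   full schedule stays at its [train_config()] default).
#' @param batch,lr0 training overrides passed to [train_config()].
#' @param iou_thr,conf_thr,nms_iou evaluation parameters.
#' @param seed base RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(channels = c("RGB", "RGB+XYZ+D+F"),
                            voxel_size = 0.005, outlier_k = 30,
                            outlier_sigma = 2, denoise = TRUE,
                            w_chroma = 0.6, w_edge = 0.4,
                            edge_kernel = "lap4",
                            d_max = 4, xy_half = 2,
                            anchor_k = 9, ratio_threshold = 4,
                            bpr_cutoff = 0.98, kmeans_iters = 30,
                            ga_generations = 1000, ga_mut_prob = 0.9,
                            ga_sigma = 0.1,
                            epochs = 12, batch = 4, lr0 = 0.01,
                            iou_thr = 0.5, conf_thr = 0.25, nms_iou = 0.45,
                            seed = 0) {
  cfg <- as.list(environment())
  stopifnot(abs(w_chroma + w_edge - 1) < 1e-9)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# All bands the preprocessing stage can produce, in canonical order.
ALL_BANDS <- c("R", "G", "B", "C", "E", "F", "D", "X", "Y", "Z")

#' Parse a channel-configuration string
#'
#' Splits a specification such as `"RGB+XYZ+D+F"` on `+` and expands the
#' tokens RGB, R-G (chroma, band C), E (edge), F, D and XYZ into band names
#' in canonical order \[R,G,B,C,E,F,D,X,Y,Z\].
#'
#' @param spec configuration string.
#' @return character vector of band names.
#' @export
parse_channels <- function(spec) {
  toks <- strsplit(gsub("[()\\s]", "", spec, perl = TRUE), "+", fixed = TRUE)[[1]]
  bands <- character(0)
  for (tk in toks) {
    bands <- c(bands, switch(toupper(tk),
      "RGB" = c("R", "G", "B"),
      "R-G" = "C",
      "E" = "E",
      "F" = "F",
      "D" = "D",
      "XYZ" = c("X", "Y", "Z"),
      stop("unknown channel token: ", tk)))
  }
  if (anyDuplicated(bands)) stop("duplicate bands in channel spec: ", spec)
  ALL_BANDS[ALL_BANDS %in% bands]
}

#' Preprocess one raw scene into a multi-channel stack
#'
#' Runs the full fusion flow: point-cloud cleaning (voxel downsampling and,
#' optionally, statistical outlier removal), feature extraction (chroma,
#' edge, key feature), depth decoding, XYZ rasterization through the camera
#' chain, and band stacking honoring the requested channel selection.
#'
#' @param scene a raw scene as produced by [generate_scene()] (fields `rgb`,
#'   `depth_raw`, `cloud`, plus `K` and `off`; a list of `frames` may replace
#'   `cloud` for multi-frame input).
#' @param cfg a [pipeline_config()].
#' @param channels channel specification string (default: first entry of
#'   `cfg$channels`).
#' @return H x W x m array with named bands; attribute `log` carries
#'   per-stage counts (points in/kept/removed, zero-filled XYZ pixels).
#' @export
run_preprocess <- function(scene, cfg = pipeline_config(),
                           channels = cfg$channels[1]) {
  bands <- parse_channels(channels)
  K <- scene$K; off <- scene$off %||% projection_offsets()
  cloud <- if (!is.null(scene$frames)) accumulate_frames(scene$frames) else scene$cloud
  n_in <- n_points(cloud)
  cloud <- voxel_downsample(cloud, cfg$voxel_size)
  n_voxel <- n_points(cloud)
  n_removed <- 0L
  if (isTRUE(cfg$denoise) && n_voxel > cfg$outlier_k) {
    res <- remove_outliers(cloud, k = cfg$outlier_k, sigma_mult = cfg$outlier_sigma)
    cloud <- res$cloud
    n_removed <- length(res$removed)
  }
  rgb <- scene$rgb
  feats <- extract_features(rgb, cfg$w_chroma, cfg$w_edge, cfg$edge_kernel)
  d <- decode_depth(scene$depth_raw, cfg$d_max)
  xyz <- xyz_raster(cloud, K, extrinsics(), off)
  lib <- list(R = rgb[, , 1] / 255, G = rgb[, , 2] / 255, B = rgb[, , 3] / 255,
              C = feats$chroma, E = feats$edge, F = feats$F, D = d,
              X = xyz[, , 1], Y = xyz[, , 2], Z = xyz[, , 3])
  out <- array(0, dim = c(dim(rgb)[1:2], length(bands)),
               dimnames = list(NULL, NULL, bands))
  for (b in bands) out[, , b] <- lib[[b]]
  attr(out, "log") <- list(points_in = n_in, points_after_voxel = n_voxel,
                           points_removed = n_removed,
                           points_kept = n_points(cloud),
                           n_zero_filled = attr(xyz, "n_zero_filled"))
  out
}

# Training-time view: geometric bands scaled to O(1); appearance bands are
# already in [0, 1]. Raw meters stay in the containers.
training_view <- function(stack, d_max = 4, xy_half = 2) {
  bands <- dimnames(stack)[[3]]
  for (b in intersect(bands, c("D", "Z"))) stack[, , b] <- stack[, , b] / d_max
  for (b in intersect(bands, c("X", "Y"))) {
    stack[, , b] <- stack[, , b] / xy_half
  }
  stack
}

#' Run the channel-configuration comparison experiment
#'
#' Generates a synthetic dataset, preprocesses every scene once to the full
#' band library, then for each requested channel configuration and each
#' training seed: checks/re-estimates anchors on the training labels, builds
#' the detector with the matching input-layer channel count, trains it under
#' the shared budget, and evaluates P/R/F1 on the test split.
#'
#' @param cfg a [pipeline_config()].
#' @param n_scenes number of synthetic scenes (70/10/20 split).
#' @param params a [scene_params()] template.
#' @param K a [camera_intrinsics()].
#' @param seeds training seeds; one run per (configuration, seed).
#' @param backend `"cnn"` (train the detector) or `"oracle"` (perfect
#'   detector; plumbing check).
#' @param verbose print progress.
#' @return data.frame with one row per (configuration, seed): `config`,
#'   `nc`, `seed`, `P`, `R`, `F1`. Attribute `summary` holds the per-config
#'   median F1.
#' @export
run_experiment <- function(cfg = pipeline_config(), n_scenes = 60,
                           params = scene_params(), K = default_intrinsics(4),
                           seeds = cfg$seed + 0:2, backend = c("cnn", "oracle"),
                           verbose = FALSE) {
  backend <- match.arg(backend)
  ds <- make_dataset(n_scenes, params, K, seed = cfg$seed)
  full_spec <- "RGB+(R-G)+E+F+D+XYZ"  # superset; configs subset these bands
  stacks <- lapply(ds$scenes, function(sc) {
    st <- run_preprocess(sc, cfg, channels = full_spec)
    training_view(st, cfg$d_max, cfg$xy_half)
  })
  is_train <- ds$manifest$split == "train"
  is_test <- ds$manifest$split == "test"
  train_boxes <- do.call(rbind, lapply(ds$scenes[is_train], `[[`, "labels"))
  rows <- list()
  for (config in cfg$channels) {
    bands <- parse_channels(config)
    m <- length(bands)
    if (m < 3 || m > 8) {
      stop(sprintf("configuration %s resolves to %d bands (need 3-8)", config, m))
    }
    subset_split <- function(sel) {
      lapply(which(sel), function(i) {
        x <- stacks[[i]][, , bands, drop = FALSE]
        list(x = x, boxes = ds$scenes[[i]]$labels)
      })
    }
    dtrain <- subset_split(is_train)
    dtest <- subset_split(is_test)
    for (sd in seeds) {
      if (backend == "oracle") {
        ev <- evaluate("oracle", dtest, cfg$iou_thr)
      } else {
        anchors <- check_anchors(train_boxes,
                                 defaults = default_anchors(cfg$ratio_threshold,
                                                            cfg$bpr_cutoff),
                                 k = cfg$anchor_k, iters = cfg$kmeans_iters,
                                 generations = cfg$ga_generations,
                                 mut_prob = cfg$ga_mut_prob,
                                 sigma = cfg$ga_sigma, seed = sd)
        model <- build_model(input_layer_spec(m), anchors, seed = sd)
        tc <- train_config(batch = cfg$batch, lr0 = cfg$lr0, seed = sd)
        model <- train(model, dtrain, tc, epochs = cfg$epochs,
                       verbose = verbose)
        ev <- evaluate(model, dtest, cfg$iou_thr, cfg$conf_thr, cfg$nms_iou)
      }
      if (verbose) {
        message(sprintf("%s (m=%d) seed %d: P %.1f R %.1f F1 %.2f",
                        config, m, sd, ev$P, ev$R, ev$F1))
      }
      rows[[length(rows) + 1]] <- data.frame(config = config, nc = m,
                                             seed = sd, P = ev$P, R = ev$R,
                                             F1 = ev$F1)
    }
  }
  out <- do.call(rbind, rows)
  summ <- aggregate(F1 ~ config + nc, data = out, FUN = median)
  names(summ)[3] <- "median_F1"
  attr(out, "summary") <- summ[order(summ$nc), ]
  out
}
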