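# Compact anchor-based single-stage detector with a configurable m-channel
# input layer (6x6 stride-2, 32 filters), a small convolutional trunk and a
# single-scale detection head, plus training and P/R/F1 evaluation.

#' Input layer specification
#'
#' The detector's first convolution has kernel W x H x m x n: 6 x 6 spatial
#' extent, m input channels (3 for plain RGB up to 8 for the full
#' \[R,G,B,F,D,X,Y,Z\] stack) and 32 filters. Only m varies with the channel
#' configuration; W, H and n stay fixed.
#'
#' @param m input channel count, between 3 and 8.
#' @param kernel spatial kernel size (default 6).
#' @param filters output filter count (default 32).
#' @return object of class `input_layer_spec`.
#' @export
input_layer_spec <- function(m, kernel = 6, filters = 32) {
  stopifnot(m >= 3, m <= 8, kernel >= 1, filters >= 1)
  structure(list(kernel = as.integer(kernel), m = as.integer(m),
                 filters = as.integer(filters)), class = "input_layer_spec")
}

#' Training configuration
#'
#' SGD hyperparameters: batch size 4, initial learning rate 0.01 with linear
#' decay to 0.01 of its initial value, momentum 0.937 (0.8 during warm-up),
#' L2 regularization 0.0005, and a 3-epoch warm-up with the bias learning
#' rate fixed at 0.1.
#'
#' @param batch batch size.
#' @param lr0 initial learning rate.
#' @param lr_decay final learning-rate fraction of `lr0`.
#' @param momentum SGD momentum after warm-up.
#' @param warmup_momentum momentum during warm-up.
#' @param weight_decay L2 regularization factor (weights only).
#' @param warmup_epochs warm-up length in epochs.
#' @param warmup_bias_lr bias learning rate at the start of warm-up.
#' @param max_epochs training epochs.
#' @param lambda_box box-regression loss weight.
#' @param seed RNG seed for shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch = 4, lr0 = 0.01, lr_decay = 0.01,
                         momentum = 0.937, warmup_momentum = 0.8,
                         weight_decay = 5e-4, warmup_epochs = 3,
                         warmup_bias_lr = 0.1, max_epochs = 200,
                         lambda_box = 5, seed = 0) {
  stopifnot(batch >= 1, lr0 > 0, lr_decay > 0, momentum > 0,
            weight_decay >= 0, warmup_epochs >= 0, max_epochs >= 1,
            warmup_epochs < max_epochs)
  structure(list(batch = as.integer(batch), lr0 = lr0, lr_decay = lr_decay,
                 momentum = momentum, warmup_momentum = warmup_momentum,
                 weight_decay = weight_decay, warmup_epochs = warmup_epochs,
                 warmup_bias_lr = warmup_bias_lr,
                 max_epochs = as.integer(max_epochs),
                 lambda_box = lambda_box, seed = seed),
            class = "train_config")
}

#' Build the compact detector model
#'
#' First layer: `kernel x kernel` (6 x 6) stride-2 convolution with `m`
#' input channels and 32 filters. Trunk: three 3 x 3 convolutions (two of
#' them stride 2), each followed by a parameter-free per-channel spatial
#' normalization and a leaky-ReLU, then a 1 x 1 anchor-based head
#' predicting (objectness, tx, ty, tw, th) per anchor at each cell of a
#' single-scale grid with total stride 8.
#'
#' @param spec an [input_layer_spec()].
#' @param anchors an [anchor_set()] giving the (w, h) priors in pixels.
#' @param seed RNG seed for weight initialization.
#' @return object of class `detector_model`.
#' @export
build_model <- function(spec, anchors, seed = 0) {
  stopifnot(inherits(spec, "input_layer_spec"), inherits(anchors, "anchor_set"))
  nA <- nrow(anchors$wh)
  layers <- with_seed(seed, list(
    make_conv_layer(spec$kernel, spec$kernel, spec$m, spec$filters,
                    stride = 2, pad = 2, act = "leaky", norm = TRUE),
    make_conv_layer(3, 3, spec$filters, 48, stride = 2, pad = 1,
                    act = "leaky"),
    make_conv_layer(3, 3, 48, 64, stride = 2, pad = 1, act = "leaky"),
    make_conv_layer(3, 3, 64, 64, stride = 1, pad = 1, act = "leaky"),
    make_conv_layer(1, 1, 64, 5L * nA, stride = 1, pad = 0, act = "linear")
  ))
  # start objectness near a low prior so early training is stable
  obj_idx <- 5 * (seq_len(nA) - 1) + 1
  layers[[5]]$b[obj_idx] <- -4
  structure(list(spec = spec, anchors = anchors, layers = layers,
                 stride = 8L), class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model m=%d, %d layers, %d anchors, %d parameters>\n",
              x$spec$m, length(x$layers), nrow(x$anchors$wh),
              sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))))
  invisible(x)
}

#' Per-layer parameter counts of a detector
#'
#' @param model a `detector_model`.
#' @return integer vector, weights plus biases per layer; the first entry is
#'   kernel^2 * m * filters + filters.
#' @export
layer_param_counts <- function(model) {
  vapply(model$layers, function(l) length(l$W) + length(l$b), integer(1))
}

#' Per-layer output shapes for a given input size
#'
#' @param model a `detector_model`.
#' @param height,width input raster size in pixels.
#' @return list of c(H, W, C) per layer.
#' @export
layer_output_shapes <- function(model, height, width) {
  shapes <- vector("list", length(model$layers))
  H <- height; W <- width
  for (i in seq_along(model$layers)) {
    hw <- conv_out_hw(model$layers[[i]], H, W)
    shapes[[i]] <- c(hw, model$layers[[i]]$cout)
    H <- hw[1]; W <- hw[2]
  }
  shapes
}

check_input_channels <- function(model, x) {
  if (dim(x)[3] != model$spec$m) {
    stop(sprintf("model expects %d input channels, batch has %d",
                 model$spec$m, dim(x)[3]))
  }
  invisible(x)
}

# Build objectness/box regression targets for one image on the head grid.
# A ground-truth box is assigned to every anchor matching it within the
# ratio threshold, at its center cell and at the two nearest neighbouring
# cells; the bounded decode (2*sigmoid - 0.5 for centers, (2*sigmoid)^2 for
# sizes) can reach all of these. Dense assignment speeds up objectness
# learning; near-duplicate detections collapse in NMS.
detector_targets <- function(model, boxes, height, width, gh, gw) {
  nA <- nrow(model$anchors$wh)
  sy <- height / gh; sx <- width / gw
  obj <- array(0, dim = c(gh, gw, nA))
  tbox <- array(0, dim = c(gh, gw, nA, 4))
  boxes <- as_box_df(boxes)
  if (nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      w <- boxes$xmax[i] - boxes$xmin[i]; h <- boxes$ymax[i] - boxes$ymin[i]
      if (w <= 0 || h <= 0) next
      cx <- (boxes$xmin[i] + boxes$xmax[i]) / 2
      cy <- (boxes$ymin[i] + boxes$ymax[i]) / 2
      fx <- cx / sx; fy <- cy / sy
      gx <- min(max(floor(fx), 0), gw - 1)
      gy <- min(max(floor(fy), 0), gh - 1)
      cells <- rbind(c(gx, gy),
                     c(gx + if (fx - gx < 0.5) -1 else 1, gy),
                     c(gx, gy + if (fy - gy < 0.5) -1 else 1))
      cells <- cells[cells[, 1] >= 0 & cells[, 1] < gw &
                     cells[, 2] >= 0 & cells[, 2] < gh, , drop = FALSE]
      ratios <- ratio_metric(cbind(w, h), model$anchors$wh)[1, ]
      matched <- which(ratios < model$anchors$ratio_threshold)
      if (length(matched) == 0L) matched <- which.min(ratios)
      for (a in matched) {
        for (ci in seq_len(nrow(cells))) {
          j <- cells[ci, 1]; k <- cells[ci, 2]
          ox <- fx - j; oy <- fy - k
          if (ox < -0.5 || ox > 1.5 || oy < -0.5 || oy > 1.5) next
          obj[k + 1, j + 1, a] <- 1
          tbox[k + 1, j + 1, a, ] <- c(ox, oy,
                                       w / model$anchors$wh[a, 1],
                                       h / model$anchors$wh[a, 2])
        }
      }
    }
  }
  list(obj = obj, tbox = tbox, sx = sx, sy = sy)
}

# Loss and gradient w.r.t. the raw head output for one image.
# Channel layout per anchor a: [obj, tx, ty, tw, th].
detector_loss <- function(model, head, boxes, height, width, lambda_box = 5) {
  d <- dim(head)
  gh <- d[1]; gw <- d[2]
  nA <- nrow(model$anchors$wh)
  tg <- detector_targets(model, boxes, height, width, gh, gw)
  grad <- array(0, dim = d)
  loss <- 0
  n_all <- gh * gw * nA
  pos <- which(tg$obj == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  n_neg <- max(1, n_all - n_pos)
  for (a in seq_len(nA)) {
    ch <- 5 * (a - 1)
    p <- sigmoid(head[, , ch + 1])
    y <- tg$obj[, , a]
    # soft objectness targets: a positive cell is trained towards the IoU of
    # its currently decoded box with the ground truth, so badly localized
    # duplicates earn low confidence and are cut by the confidence threshold
    soft <- y
    if (n_pos > 0) {
      sel <- pos[pos[, 3] == a, , drop = FALSE]
      if (nrow(sel) > 0) {
        for (r in seq_len(nrow(sel))) {
          i <- sel[r, 1]; j <- sel[r, 2]
          tgt <- tg$tbox[i, j, a, ]
          sxy <- sigmoid(head[i, j, ch + 2:3])
          pxy <- 2 * sxy - 0.5
          res_xy <- pxy - tgt[1:2]
          swh <- sigmoid(head[i, j, ch + 4:5])
          qwh <- 2 * swh
          res_wh <- qwh - sqrt(tgt[3:4])
          loss <- loss + lambda_box / n_pos * (sum(res_xy^2) + sum(res_wh^2))
          grad[i, j, ch + 2:3] <- 4 * lambda_box / n_pos * res_xy * sxy * (1 - sxy)
          grad[i, j, ch + 4:5] <- 4 * lambda_box / n_pos * res_wh * swh * (1 - swh)
          # IoU of the decoded and target boxes, in cell units
          aw <- model$anchors$wh[a, 1] / tg$sx; ah <- model$anchors$wh[a, 2] / tg$sy
          pw <- qwh[1]^2 * aw; ph <- qwh[2]^2 * ah
          tw <- tgt[3] * aw; th <- tgt[4] * ah
          ix <- max(0, min(pxy[1] + pw / 2, tgt[1] + tw / 2) -
                       max(pxy[1] - pw / 2, tgt[1] - tw / 2))
          iy <- max(0, min(pxy[2] + ph / 2, tgt[2] + th / 2) -
                       max(pxy[2] - ph / 2, tgt[2] - th / 2))
          inter <- ix * iy
          soft[i, j] <- inter / max(pw * ph + tw * th - inter, 1e-9)
        }
      }
    }
    eps <- 1e-12
    bce <- -(soft * log(p + eps) + (1 - soft) * log(1 - p + eps))
    # mean BCE over the grid with a moderate positive up-weight: enough to
    # lift the rare positives against the overwhelming background mass
    wgt <- ifelse(y == 1, 10, 1) / n_all
    loss <- loss + sum(bce * wgt)
    grad[, , ch + 1] <- (p - soft) * wgt
  }
  list(loss = loss, grad = grad)
}

#' Train the detector by SGD
#'
#' Mini-batch stochastic gradient descent with momentum, warm-up and linear
#' learning-rate decay per [sgd_schedule()]; L2 weight decay applied to
#' convolution weights only. Runs on samples of the form
#' `list(x = H x W x m array, boxes = data.frame)`.
#'
#' @param model a `detector_model`.
#' @param dataset non-empty list of samples with channel count matching the
#'   model.
#' @param cfg a [train_config()].
#' @param epochs number of epochs to run (default `cfg$max_epochs`).
#' @param augment apply training augmentation (horizontal flip, color gain,
#'   noise) to each sample (default TRUE).
#' @param ema_decay optional per-step exponential-moving-average decay for
#'   the returned weights (this detector family's usual stabilizer on long
#'   schedules). The default `NULL` returns the raw final weights, which at
#'   short desk-scale budgets outperform the lagging average.
#' @param verbose print a line per epoch.
#' @return the trained model, with attribute `loss_history` (mean per-image
#'   loss per epoch).
#' @export
train <- function(model, dataset, cfg = train_config(),
                  epochs = cfg$max_epochs, augment = TRUE, ema_decay = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "detector_model"), inherits(cfg, "train_config"))
  if (!is.list(dataset) || length(dataset) == 0L) {
    stop("`dataset` must be a non-empty list of samples")
  }
  for (s in dataset) check_input_channels(model, s$x)
  vel <- lapply(model$layers, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
  })
  ema <- if (!is.null(ema_decay)) {
    lapply(model$layers, function(l) list(W = l$W, b = l$b))
  }
  step <- 0L
  n <- length(dataset)
  nbatch <- ceiling(n / cfg$batch)
  history <- numeric(epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bi in seq_len(nbatch)) {
        idx <- ord[((bi - 1) * cfg$batch + 1):min(bi * cfg$batch, n)]
        sched <- sgd_schedule(cfg, ep, (bi - 1) / nbatch)
        acc <- lapply(model$layers, function(l) {
          list(dW = matrix(0, nrow(l$W), ncol(l$W)), db = numeric(length(l$b)))
        })
        for (ii in idx) {
          s <- dataset[[ii]]
          if (augment) s <- augment_sample(s)
          fw <- net_forward(model$layers, s$x, keep_cache = TRUE)
          dims <- dim(s$x)
          ls <- detector_loss(model, fw$out, s$boxes, dims[1], dims[2],
                              cfg$lambda_box)
          ep_loss <- ep_loss + ls$loss
          gr <- net_backward(model$layers, fw$cache, ls$grad)
          for (li in seq_along(acc)) {
            acc[[li]]$dW <- acc[[li]]$dW + gr[[li]]$dW / length(idx)
            acc[[li]]$db <- acc[[li]]$db + gr[[li]]$db / length(idx)
          }
        }
        step <- step + 1L
        for (li in seq_along(model$layers)) {
          gW <- acc[[li]]$dW + cfg$weight_decay * model$layers[[li]]$W
          vel[[li]]$W <- sched$momentum * vel[[li]]$W + gW
          vel[[li]]$b <- sched$momentum * vel[[li]]$b + acc[[li]]$db
          model$layers[[li]]$W <- model$layers[[li]]$W - sched$lr_weight * vel[[li]]$W
          model$layers[[li]]$b <- model$layers[[li]]$b - sched$lr_bias * vel[[li]]$b
          if (!is.null(ema_decay)) {
            # ramp the decay in so early noisy weights wash out quickly
            d <- min(ema_decay, step / (step + 10))
            ema[[li]]$W <- d * ema[[li]]$W + (1 - d) * model$layers[[li]]$W
            ema[[li]]$b <- d * ema[[li]]$b + (1 - d) * model$layers[[li]]$b
          }
        }
      }
      history[ep] <- ep_loss / n
      if (verbose) {
        message(sprintf("epoch %d/%d loss %.4f lr %.4g mom %.3f",
                        ep, epochs, history[ep], sched$lr_weight, sched$momentum))
      }
    }
  })
  if (!is.null(ema_decay)) {
    for (li in seq_along(model$layers)) {
      model$layers[[li]]$W <- ema[[li]]$W
      model$layers[[li]]$b <- ema[[li]]$b
    }
  }
  attr(model, "loss_history") <- history
  model
}

# Training augmentation: horizontal flip (all bands + boxes; the X band's
# values change sign under a mirror, since X grows with the image column),
# and photometric gain/noise on the RGB bands only. The key-feature band is
# invariant under a pure gain (per-image min-max normalization absorbs it),
# so it is left as is.
augment_sample <- function(s) {
  d <- dim(s$x)
  bands <- dimnames(s$x)[[3]]
  if (runif(1) < 0.5) {
    s$x <- s$x[, d[2]:1, , drop = FALSE]
    dimnames(s$x)[[3]] <- bands
    if ("X" %in% bands) {
      s$x[, , "X"] <- -s$x[, , "X"]  # no-data zeros are sign-invariant
    }
    if (nrow(s$boxes) > 0) {
      xmin <- d[2] - s$boxes$xmax
      s$boxes$xmax <- d[2] - s$boxes$xmin
      s$boxes$xmin <- xmin
    }
  }
  rgb_idx <- which(bands %in% c("R", "G", "B"))
  if (length(rgb_idx) > 0) {
    gain <- runif(1, 0.8, 1.2)
    noise <- array(rnorm(d[1] * d[2] * length(rgb_idx), 0, 0.02),
                   dim = c(d[1], d[2], length(rgb_idx)))
    s$x[, , rgb_idx] <- pmin(pmax(s$x[, , rgb_idx, drop = FALSE] * gain + noise,
                                  0), 1)
  }
  s
}

#' Run the detector on one image
#'
#' Decodes the head output to boxes: center = (cell + sigmoid(txy)) * stride,
#' size = anchor * (2 * sigmoid(twh))^2 (bounded decode); keeps detections with objectness confidence at
#' or above `conf_thr`, clips to the image, and applies greedy
#' non-maximum suppression.
#'
#' @param model a trained `detector_model`.
#' @param x H x W x m input array.
#' @param conf_thr confidence threshold (default 0.25).
#' @param nms_iou NMS IoU threshold (default 0.45).
#' @return data.frame of detections: `xmin`, `ymin`, `xmax`, `ymax`,
#'   `confidence`, `class`.
#' @export
predict_boxes <- function(model, x, conf_thr = 0.25, nms_iou = 0.45) {
  check_input_channels(model, x)
  d <- dim(x)
  head <- net_forward(model$layers, x)$out
  gh <- dim(head)[1]; gw <- dim(head)[2]
  sy <- d[1] / gh; sx <- d[2] / gw
  nA <- nrow(model$anchors$wh)
  dets <- list()
  for (a in seq_len(nA)) {
    ch <- 5 * (a - 1)
    conf <- sigmoid(head[, , ch + 1])
    keep <- which(conf >= conf_thr, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    gy <- keep[, 1] - 1; gx <- keep[, 2] - 1
    tx <- 2 * sigmoid(head[, , ch + 2][keep]) - 0.5
    ty <- 2 * sigmoid(head[, , ch + 3][keep]) - 0.5
    tw <- (2 * sigmoid(head[, , ch + 4][keep]))^2
    th <- (2 * sigmoid(head[, , ch + 5][keep]))^2
    cx <- (gx + tx) * sx; cy <- (gy + ty) * sy
    w <- model$anchors$wh[a, 1] * tw; h <- model$anchors$wh[a, 2] * th
    dets[[a]] <- data.frame(xmin = cx - w / 2, ymin = cy - h / 2,
                            xmax = cx + w / 2, ymax = cy + h / 2,
                            confidence = conf[keep], class = 0L)
  }
  dets <- do.call(rbind, dets)
  if (is.null(dets) || nrow(dets) == 0) {
    return(data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
                      ymax = numeric(0), confidence = numeric(0),
                      class = integer(0)))
  }
  dets$xmin <- pmax(dets$xmin, 0); dets$ymin <- pmax(dets$ymin, 0)
  dets$xmax <- pmin(dets$xmax, d[2]); dets$ymax <- pmin(dets$ymax, d[1])
  nms_boxes(dets, nms_iou)
}

# Greedy NMS in descending confidence.
nms_boxes <- function(dets, iou_thr) {
  ord <- order(dets$confidence, decreasing = TRUE)
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  active <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!active[i]) next
    keep[i] <- TRUE
    if (i < nrow(dets)) {
      rest <- which(active & seq_len(nrow(dets)) > i)
      if (length(rest) > 0) {
        iou <- box_iou(dets[i, , drop = FALSE], dets[rest, , drop = FALSE])[1, ]
        active[rest[iou > iou_thr]] <- FALSE
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
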