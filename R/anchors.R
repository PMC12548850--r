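# Anchor-box adequacy check (AAT / BPR), k-means re-estimation in normalized
# (w, h) space, and elitist genetic refinement of the anchor dimensions.

#' Anchor set
#'
#' An ordered list of (width, height) priors in pixels, kept sorted by area,
#' with the adequacy parameters attached.
#'
#' @param wh n x 2 matrix or data.frame of positive widths and heights.
#' @param ratio_threshold width/height ratio beyond which a box and an anchor
#'   are considered mismatched (default 4).
#' @param bpr_cutoff best-possible-recall level above which the current
#'   anchors are deemed adequate (default 0.98).
#' @return object of class `anchor_set`.
#' @export
anchor_set <- function(wh, ratio_threshold = 4, bpr_cutoff = 0.98) {
  wh <- as.matrix(wh)
  stopifnot(ncol(wh) == 2, all(wh > 0), ratio_threshold > 1,
            bpr_cutoff > 0, bpr_cutoff <= 1)
  wh <- wh[order(wh[, 1] * wh[, 2]), , drop = FALSE]
  colnames(wh) <- c("w", "h")
  rownames(wh) <- NULL
  structure(list(wh = wh, ratio_threshold = ratio_threshold,
                 bpr_cutoff = bpr_cutoff), class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set n=%d, ratio_threshold=%g, bpr_cutoff=%g>\n",
              nrow(x$wh), x$ratio_threshold, x$bpr_cutoff))
  print(x$wh)
  invisible(x)
}

#' Default detector anchor dimensions
#'
#' The nine (width, height) priors commonly used across single-stage
#' detector scales, in pixels.
#'
#' @inheritParams anchor_set
#' @return an [anchor_set()] with 9 anchors.
#' @export
default_anchors <- function(ratio_threshold = 4, bpr_cutoff = 0.98) {
  wh <- matrix(c(10, 13, 16, 30, 33, 23, 30, 61, 62, 45, 59, 119,
                 116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE)
  anchor_set(wh, ratio_threshold, bpr_cutoff)
}

as_wh_matrix <- function(boxes) {
  if (inherits(boxes, "anchor_set")) return(boxes$wh)
  if (is.data.frame(boxes)) {
    if (all(c("w", "h") %in% names(boxes))) {
      boxes <- cbind(boxes$w, boxes$h)
    } else if (all(c("xmin", "xmax", "ymin", "ymax") %in% names(boxes))) {
      boxes <- cbind(boxes$xmax - boxes$xmin, boxes$ymax - boxes$ymin)
    }
  }
  m <- as.matrix(boxes)
  if (is.null(dim(m)) || ncol(m) != 2) stop("expected (width, height) pairs")
  storage.mode(m) <- "double"
  m
}

#' Width/height ratio mismatch metric
#'
#' r = max(w/wa, wa/w, h/ha, ha/h) >= 1, with r = 1 iff the box matches the
#' anchor exactly.
#'
#' @param boxes n x 2 (width, height) pairs in pixels.
#' @param anchors m x 2 (width, height) pairs in pixels.
#' @return n x m matrix of ratios.
#' @export
ratio_metric <- function(boxes, anchors) {
  b <- as_wh_matrix(boxes); a <- as_wh_matrix(anchors)
  if (any(b <= 0) || any(a <= 0)) stop("box and anchor dimensions must be positive")
  rw <- outer(b[, 1], a[, 1], `/`)
  rh <- outer(b[, 2], a[, 2], `/`)
  pmax(pmax(rw, 1 / rw), pmax(rh, 1 / rh))
}

#' Anchors Above Threshold (AAT)
#'
#' Mean over boxes of the fraction of anchors matching the box within the
#' ratio threshold: the average per-box matched-anchor rate.
#'
#' @param boxes n x 2 (width, height) pairs (or a label data.frame).
#' @param anchors an [anchor_set()].
#' @return fraction in \[0, 1\].
#' @export
aat <- function(boxes, anchors) {
  b <- as_wh_matrix(boxes)
  if (nrow(b) == 0L) stop("`boxes` must be non-empty")
  stopifnot(inherits(anchors, "anchor_set"))
  r <- ratio_metric(b, anchors$wh)
  mean(rowSums(r < anchors$ratio_threshold) / nrow(anchors$wh))
}

#' Best Possible Recall (BPR)
#'
#' Fraction of boxes whose best anchor matches within the ratio threshold:
#' an upper bound on the recall attainable with this anchor set.
#'
#' @inheritParams aat
#' @return fraction in \[0, 1\].
#' @export
bpr <- function(boxes, anchors) {
  b <- as_wh_matrix(boxes)
  if (nrow(b) == 0L) stop("`boxes` must be non-empty")
  stopifnot(inherits(anchors, "anchor_set"))
  r <- ratio_metric(b, anchors$wh)
  mean(apply(r, 1, min) < anchors$ratio_threshold)
}

#' Anchor re-estimation by k-means in normalized (w, h) space
#'
#' Box dimensions are normalized to \[0, 1\] by the per-axis maximum,
#' clustered by Lloyd's algorithm (30 iterations by default, seeded
#' initialization from k distinct boxes), de-normalized and area-sorted.
#' Empty clusters keep their previous centroid.
#'
#' @param boxes n x 2 (width, height) pairs; needs >= k distinct rows.
#' @param k number of anchors (default 9).
#' @param iters Lloyd iterations (default 30).
#' @param seed RNG seed for the initialization.
#' @inheritParams anchor_set
#' @return an [anchor_set()]; attribute `objective_trace` holds the
#'   within-cluster sum of squared normalized distances after each iteration.
#' @export
kmeans_anchors <- function(boxes, k = 9, iters = 30, seed = 0,
                           ratio_threshold = 4, bpr_cutoff = 0.98) {
  b <- as_wh_matrix(boxes)
  distinct <- unique(b)
  if (nrow(distinct) < k) {
    stop(sprintf("need at least %d distinct boxes, got %d", k, nrow(distinct)))
  }
  axis_max <- apply(b, 2, max)
  bn <- sweep(b, 2, axis_max, `/`)
  dn <- unique(bn)
  centers <- with_seed(seed, dn[sample.int(nrow(dn), k), , drop = FALSE])
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    d2 <- outer(bn[, 1], centers[, 1], `-`)^2 + outer(bn[, 2], centers[, 2], `-`)^2
    assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) centers[j, ] <- colMeans(bn[sel, , drop = FALSE])
    }
    d2 <- outer(bn[, 1], centers[, 1], `-`)^2 + outer(bn[, 2], centers[, 2], `-`)^2
    trace[it] <- sum(d2[cbind(seq_len(nrow(bn)), max.col(-d2, ties.method = "first"))])
  }
  out <- anchor_set(sweep(centers, 2, axis_max, `*`), ratio_threshold, bpr_cutoff)
  attr(out, "objective_trace") <- trace
  out
}

#' Anchor fitness under the ratio threshold
#'
#' Mean over boxes of 1 / r_best, counted only when the best anchor matches
#' within the ratio threshold; mismatched boxes (and hence overly diminutive
#' anchors) contribute zero.
#'
#' @inheritParams aat
#' @param anchors an [anchor_set()] or n x 2 matrix.
#' @param ratio_threshold used when `anchors` is a bare matrix.
#' @return scalar fitness in \[0, 1\].
#' @export
anchor_fitness <- function(boxes, anchors, ratio_threshold = 4) {
  b <- as_wh_matrix(boxes)
  if (inherits(anchors, "anchor_set")) {
    ratio_threshold <- anchors$ratio_threshold
    anchors <- anchors$wh
  }
  r_best <- apply(ratio_metric(b, anchors), 1, min)
  mean(ifelse(r_best < ratio_threshold, 1 / r_best, 0))
}

#' Genetic refinement of an anchor set
#'
#' Elitist single-population search: each generation mutates the incumbent
#' anchor dimensions multiplicatively (per-dimension factor drawn near 1 with
#' probability `mut_prob` and spread `sigma`, clipped to \[0.3, 3\]) and keeps
#' the candidate iff its [anchor_fitness()] improves. Returns the best-ever
#' set, area-sorted.
#'
#' @param init an [anchor_set()] to start from.
#' @param boxes n x 2 (width, height) pairs.
#' @param generations mutation rounds (default 1000).
#' @param mut_prob per-dimension mutation probability (default 0.9).
#' @param sigma mutation spread (default 0.1).
#' @param seed RNG seed.
#' @return an [anchor_set()]; attribute `fitness_trace` holds the best-ever
#'   fitness after each generation, attribute `fitness` the final value.
#' @export
ga_refine <- function(init, boxes, generations = 1000, mut_prob = 0.9,
                      sigma = 0.1, seed = 0) {
  stopifnot(inherits(init, "anchor_set"))
  b <- as_wh_matrix(boxes)
  if (nrow(b) == 0L) stop("`boxes` must be non-empty")
  best <- init$wh
  best_fit <- anchor_fitness(b, best, init$ratio_threshold)
  trace <- numeric(generations)
  if (generations > 0) {
    with_seed(seed, {
      for (g in seq_len(generations)) {
        factor <- matrix(1, nrow(best), 2)
        mut <- matrix(runif(length(best)) < mut_prob, nrow(best), 2)
        factor[mut] <- pmin(pmax(1 + rnorm(sum(mut), 0, sigma), 0.3), 3)
        cand <- best * factor
        fit <- anchor_fitness(b, cand, init$ratio_threshold)
        if (fit > best_fit) {
          best <- cand
          best_fit <- fit
        }
        trace[g] <- best_fit
      }
    })
  }
  out <- anchor_set(best, init$ratio_threshold, init$bpr_cutoff)
  attr(out, "fitness_trace") <- trace
  attr(out, "fitness") <- best_fit
  out
}

#' Anchor adequacy check with automatic re-estimation
#'
#' Computes the BPR of the default anchors on the training boxes; if it
#' reaches the cutoff the defaults are returned unchanged, otherwise the
#' anchors are re-estimated by [kmeans_anchors()] and refined by
#' [ga_refine()]. The returned set never has a lower BPR than the defaults.
#'
#' @param boxes n x 2 (width, height) pairs from the training labels.
#' @param defaults an [anchor_set()] to check first (default
#'   [default_anchors()]).
#' @param k,iters,seed passed to [kmeans_anchors()].
#' @param generations,mut_prob,sigma passed to [ga_refine()].
#' @return an [anchor_set()]; attribute `recalculated` says whether the
#'   defaults were replaced.
#' @export
check_anchors <- function(boxes, defaults = default_anchors(), k = nrow(defaults$wh),
                          iters = 30, generations = 1000, mut_prob = 0.9,
                          sigma = 0.1, seed = 0) {
  b <- as_wh_matrix(boxes)
  bpr_default <- bpr(b, defaults)
  if (bpr_default >= defaults$bpr_cutoff) {
    attr(defaults, "recalculated") <- FALSE
    attr(defaults, "bpr") <- bpr_default
    return(defaults)
  }
  km <- kmeans_anchors(b, k = k, iters = iters, seed = seed,
                       ratio_threshold = defaults$ratio_threshold,
                       bpr_cutoff = defaults$bpr_cutoff)
  ga <- ga_refine(km, b, generations = generations, mut_prob = mut_prob,
                  sigma = sigma, seed = seed)
  # contract: never return a set worse (by BPR) than the defaults
  out <- if (bpr(b, ga) >= bpr_default) ga else defaults
  attr(out, "recalculated") <- TRUE
  attr(out, "bpr") <- bpr(b, out)
  out
}
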