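# Detection matching and P/R/F1 evaluation.

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching in descending confidence: each prediction
#' claims the unmatched truth of highest IoU, provided that IoU reaches
#' `iou_thr`. Count conservation holds on every input: TP + FP = #preds and
#' TP + FN = #truths.
#'
#' @param preds data.frame of detections with `xmin`, `ymin`, `xmax`,
#'   `ymax` and `confidence`.
#' @param truths data.frame of ground-truth boxes (same coordinate columns).
#' @param iou_thr IoU threshold in (0, 1) for a true positive (default 0.5).
#' @return list with integer `tp`, `fp`, `fn` and a logical `matched_pred`
#'   flag per prediction (in the input order of `preds`).
#' @export
match_detections <- function(preds, truths, iou_thr = 0.5) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  preds <- as_box_df(preds)
  truths <- as_box_df(truths)
  np <- nrow(preds); nt <- nrow(truths)
  matched_pred <- logical(np)
  if (np > 0 && nt > 0) {
    conf <- if ("confidence" %in% names(preds)) preds$confidence else rep(1, np)
    ord <- order(conf, decreasing = TRUE)
    iou <- box_iou(preds, truths)
    truth_taken <- logical(nt)
    for (i in ord) {
      cand <- which(!truth_taken & iou[i, ] >= iou_thr)
      if (length(cand) > 0) {
        best <- cand[which.max(iou[i, cand])]
        truth_taken[best] <- TRUE
        matched_pred[i] <- TRUE
      }
    }
  }
  tp <- sum(matched_pred)
  list(tp = as.integer(tp), fp = as.integer(np - tp), fn = as.integer(nt - tp),
       matched_pred = matched_pred)
}

#' Precision, recall and F1 score (percent)
#'
#' P = TP/(TP+FP) * 100, R = TP/(TP+FN) * 100, F1 = 2PR/(P+R). A zero
#' denominator yields 0 with a warning.
#'
#' @param tp,fp,fn nonnegative counts.
#' @return percentage in \[0, 100\].
#' @export
precision_pct <- function(tp, fp) {
  if (tp + fp == 0) {
    warning("no predictions: precision defined as 0")
    return(0)
  }
  tp / (tp + fp) * 100
}

#' @rdname precision_pct
#' @export
recall_pct <- function(tp, fn) {
  if (tp + fn == 0) {
    warning("no ground-truth boxes: recall defined as 0")
    return(0)
  }
  tp / (tp + fn) * 100
}

#' @rdname precision_pct
#' @param p,r precision and recall in percent.
#' @export
f1_score <- function(p, r) {
  if (p + r == 0) {
    warning("P + R = 0: F1 defined as 0")
    return(0)
  }
  2 * p * r / (p + r)
}

#' Evaluate a detector over a dataset split
#'
#' Aggregates TP/FP/FN over all images and reports precision, recall and F1
#' in percent.
#'
#' @param model a trained `detector_model`, or the string `"oracle"` for a
#'   perfect detector that returns the ground truth (plumbing check).
#' @param dataset non-empty list of samples `list(x = array, boxes = df)`.
#' @param iou_thr IoU threshold for a true positive (default 0.5).
#' @param conf_thr,nms_iou passed to [predict_boxes()].
#' @return object of class `eval_result`: list with `P`, `R`, `F1`
#'   (percent), totals `tp`, `fp`, `fn`, and a per-image count data.frame.
#' @export
evaluate <- function(model, dataset, iou_thr = 0.5, conf_thr = 0.25,
                     nms_iou = 0.45) {
  if (!is.list(dataset) || length(dataset) == 0L) stop("empty evaluation split")
  per_image <- data.frame(image = seq_along(dataset), tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    preds <- if (identical(model, "oracle")) {
      cbind(as_box_df(s$boxes), confidence = 1)
    } else {
      predict_boxes(model, s$x, conf_thr, nms_iou)
    }
    m <- match_detections(preds, s$boxes, iou_thr)
    per_image$tp[i] <- m$tp; per_image$fp[i] <- m$fp; per_image$fn[i] <- m$fn
  }
  tp <- sum(per_image$tp); fp <- sum(per_image$fp); fn <- sum(per_image$fn)
  P <- suppressWarnings(precision_pct(tp, fp))
  R <- suppressWarnings(recall_pct(tp, fn))
  structure(list(P = P, R = R, F1 = suppressWarnings(f1_score(P, R)),
                 tp = tp, fp = fp, fn = fn, per_image = per_image),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P = %.1f%%  R = %.1f%%  F1 = %.2f%%  (TP %d, FP %d, FN %d)\n",
              x$P, x$R, x$F1, x$tp, x$fp, x$fn))
  invisible(x)
}
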