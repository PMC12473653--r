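#' Detection metrics: matching, precision/recall/F1, AP and mAP50
#'
#' Single-class evaluation. Detections are matched per image: predictions
#' are visited in order of decreasing confidence and matched greedily to
#' the unmatched ground-truth box of highest IoU at or above the threshold
#' (ties broken by higher IoU, then earlier truth index); matching is
#' one-to-one, leftover truths are false negatives. Average precision is
#' the area under the all-point interpolated precision-recall curve (the
#' precision envelope made non-increasing), computed exactly.
#'
#' @name metrics
NULL

#' Match detections of one image against ground truth
#'
#' @param pred `data.frame` with columns `x1`, `y1`, `x2`, `y2`,
#'   `confidence` (0 rows allowed).
#' @param truth `data.frame`/matrix of truth corner boxes (columns
#'   `x1`, `y1`, `x2`, `y2`).
#' @param iou_thr IoU threshold defining a true positive.
#' @return `pred` with added logical column `tp` and integer column
#'   `matched_truth` (NA for false positives), rows sorted by decreasing
#'   confidence; the false-negative count is attached as attribute `"fn"`.
#' @export
match_detections <- function(pred, truth, iou_thr = 0.5) {
  truth <- as.matrix(as.data.frame(truth)[, c("x1", "y1", "x2", "y2")])
  n_t <- nrow(truth)
  if (nrow(pred) == 0) {
    out <- cbind(pred, tp = logical(0), matched_truth = integer(0))
    attr(out, "fn") <- n_t
    return(out)
  }
  ord <- order(-pred$confidence)
  pred <- pred[ord, , drop = FALSE]
  used <- logical(n_t)
  tp <- logical(nrow(pred))
  matched <- rep(NA_integer_, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    if (n_t == 0) break
    p <- as.numeric(pred[i, c("x1", "y1", "x2", "y2")])
    ious <- box_iou(matrix(rep(p, n_t), ncol = 4, byrow = TRUE), truth)
    ious[used] <- -1
    j <- which.max(ious)  # ties: earlier index wins
    if (ious[j] >= iou_thr) {
      tp[i] <- TRUE
      matched[i] <- j
      used[j] <- TRUE
    }
  }
  out <- cbind(pred, tp = tp, matched_truth = matched)
  attr(out, "fn") <- n_t - sum(tp)
  out
}

#' Precision, recall and F1 from counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`.
#' Conventions: `P = 0` with no predictions, `R = 0` with no truths,
#' `F1 = 0` when `P + R = 0`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
#' @examples
#' precision_recall_f1(9, 1, 3)
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Precision-recall curve and average precision
#'
#' @param tp Logical vector of per-detection outcomes, sorted by decreasing
#'   confidence.
#' @param n_truth Total number of ground-truth boxes (> 0).
#' @param confidence Optional confidences aligned with `tp`.
#' @return A list of class `pr_curve`: `precision`, `recall`,
#'   `confidence`, `ap`.
#' @export
pr_curve <- function(tp, n_truth, confidence = NULL) {
  if (n_truth <= 0) stop("average precision is undefined without ground truth")
  ctp <- cumsum(tp)
  precision <- ctp / seq_along(tp)
  recall <- ctp / n_truth
  env <- rev(cummax(rev(precision)))
  ap <- if (length(tp) == 0) 0 else sum(diff(c(0, recall)) * env)
  structure(list(precision = precision, recall = recall,
                 confidence = confidence, ap = ap), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve: %d detections, AP = %.4f\n", length(x$precision),
              x$ap))
  invisible(x)
}

#' Evaluate a set of per-image detections
#'
#' Matches every image at the IoU threshold, pools the outcomes over the
#' dataset sorted by confidence, and computes AP (equal to mAP here, since
#' there is a single class) plus precision/recall/F1 at the best-F1
#' confidence threshold.
#'
#' @param preds List of per-image prediction `data.frame`s (columns `x1`,
#'   `y1`, `x2`, `y2`, `confidence`).
#' @param truths List (same length) of per-image truth corner boxes.
#' @param iou_thr IoU threshold (0.5 for mAP50).
#' @return A list with `map50`, `precision`, `recall`, `f1`, `threshold`,
#'   `curve`, and the pooled counts.
#' @export
evaluate_detections <- function(preds, truths, iou_thr = 0.5) {
  stopifnot(length(preds) == length(truths))
  rows <- list(); n_truth <- 0; fn <- 0
  for (i in seq_along(preds)) {
    m <- match_detections(preds[[i]], truths[[i]], iou_thr)
    n_truth <- n_truth + nrow(as.data.frame(truths[[i]]))
    fn <- fn + attr(m, "fn")
    if (nrow(m) > 0) rows[[length(rows) + 1L]] <- m[, c("confidence", "tp")]
  }
  pooled <- if (length(rows)) do.call(rbind, rows)
            else data.frame(confidence = numeric(), tp = logical())
  pooled <- pooled[order(-pooled$confidence), , drop = FALSE]
  curve <- pr_curve(pooled$tp, n_truth, pooled$confidence)
  best <- report_at_best_f1(curve, n_truth)
  list(map50 = curve$ap, precision = best["precision"],
       recall = best["recall"], f1 = best["f1"],
       threshold = best["threshold"], curve = curve,
       counts = c(tp = sum(pooled$tp), fp = sum(!pooled$tp), fn = fn,
                  n_truth = n_truth))
}

#' Operating point maximizing F1 along a PR curve
#'
#' Scans every confidence cutoff on the curve and returns precision,
#' recall, F1 and the threshold at the maximum-F1 prefix (first such prefix
#' on ties).
#'
#' @param curve A [pr_curve()].
#' @param n_truth Number of ground-truth boxes backing the curve.
#' @return Named vector `c(precision, recall, f1, threshold)`.
#' @export
report_at_best_f1 <- function(curve, n_truth) {
  n <- length(curve$precision)
  if (n == 0) return(c(precision = 0, recall = 0, f1 = 0, threshold = NA))
  f1 <- ifelse(curve$precision + curve$recall > 0,
               2 * curve$precision * curve$recall /
                 (curve$precision + curve$recall), 0)
  k <- which.max(f1)
  thr <- if (is.null(curve$confidence)) NA else curve$confidence[k]
  c(precision = curve$precision[k], recall = curve$recall[k], f1 = f1[k],
    threshold = thr)
}

#' mAP at IoU 0.5 for a list of per-image detections
#'
#' @inheritParams evaluate_detections
#' @return The mAP50 value (a single number; with one class mAP = AP).
#' @export
map50 <- function(preds, truths) {
  evaluate_detections(preds, truths, iou_thr = 0.5)$map50
}
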