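#' Detection and counting evaluation
#'
#' The evaluation suite for the detector: confusion counts from greedy
#' one-to-one matching, precision/recall/F1, average precision as the exact
#' area under the precision envelope, mAP at a fixed IoU threshold and
#' averaged over the 0.50-0.95 range, counting R-squared, and multi-class
#' accuracy.
#'
#' @name metrics
NULL

#' Match detections to ground truths within one image and class
#'
#' Greedy one-to-one matching in decreasing confidence order. A detection is
#' a true positive iff it matches a not-yet-matched ground truth with
#' IoU >= threshold (ties broken by higher IoU, then input order); unmatched
#' detections are false positives, unmatched truths false negatives.
#'
#' @param detections data.frame/matrix with columns x1, y1, x2, y2,
#'   confidence (same image and class)
#' @param ground_truths data.frame/matrix with columns x1, y1, x2, y2
#' @param iou_threshold matching threshold
#' @return list(TP, FP, FN, TN = 0, matched) where `matched` gives, per
#'   detection (in input order), the matched truth index or NA
#' @export
match_detections <- function(detections, ground_truths, iou_threshold = 0.5) {
  nd <- NROW(detections); ng <- NROW(ground_truths)
  if (nd == 0) return(list(TP = 0L, FP = 0L, FN = ng, TN = 0L,
                           matched = integer(0)))
  det <- as.data.frame(detections)
  ord <- order(-det$confidence)          # stable: ties keep input order
  matched <- rep(NA_integer_, nd)
  used <- rep(FALSE, max(ng, 1))
  if (ng > 0) {
    M <- iou_matrix(as.matrix(det[, c("x1", "y1", "x2", "y2")]),
                    as.matrix(as.data.frame(ground_truths)[
                      , c("x1", "y1", "x2", "y2")]))
    for (i in ord) {
      ious <- M[i, ]
      ious[used] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_threshold) {
        matched[i] <- j
        used[j] <- TRUE
      }
    }
  }
  tp <- sum(!is.na(matched))
  list(TP = tp, FP = nd - tp, FN = ng - tp, TN = 0L, matched = matched)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 P R / (P + R)` (the harmonic mean). Zero denominators yield 0.
#'
#' @param c a list with elements TP, FP, FN (e.g. from
#'   [match_detections()])
#' @return a number in `[0, 1]`
#' @export
precision <- function(c) {
  d <- c$TP + c$FP
  if (d == 0) 0 else c$TP / d
}

#' @rdname precision
#' @export
recall <- function(c) {
  d <- c$TP + c$FN
  if (d == 0) 0 else c$TP / d
}

#' @rdname precision
#' @param p,r precision and recall values
#' @export
f1 <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Precision-recall curve from a scored detection sweep
#'
#' @param confidences detection confidences
#' @param is_tp logical, whether each detection is a true positive
#' @param n_truth number of ground-truth objects
#' @return data.frame with confidence-sorted precision and recall columns
#' @export
pr_curve <- function(confidences, is_tp, n_truth) {
  ord <- order(-confidences)
  tp <- cumsum(is_tp[ord])
  fp <- cumsum(!is_tp[ord])
  data.frame(confidence = confidences[ord],
             precision = ifelse(tp + fp > 0, tp / (tp + fp), 0),
             recall = if (n_truth > 0) tp / n_truth else rep(0, length(tp)))
}

#' Average precision: area under the precision envelope
#'
#' Integrates P(R) exactly over the step function of the full confidence
#' sweep (all-point integration). A 101-point interpolated variant (COCO
#' style) is available via `method = "interp101"`.
#'
#' @param curve a data.frame from [pr_curve()]
#' @param method `"allpoint"` (default, exact) or `"interp101"`
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(curve, method = c("allpoint", "interp101")) {
  method <- match.arg(method)
  if (nrow(curve) == 0) return(0)
  mrec <- c(0, curve$recall)
  mpre <- c(1, curve$precision)
  # precision envelope: running max from the right
  mpre <- rev(cummax(rev(mpre)))
  if (method == "allpoint") {
    sum(diff(mrec) * mpre[-1])
  } else {
    rr <- seq(0, 1, length.out = 101)
    pe <- vapply(rr, function(r) {
      i <- which(mrec >= r)
      if (length(i)) max(mpre[i]) else 0
    }, 0)
    mean(pe)
  }
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class AP; classes without ground truths are
#' skipped (NA entries dropped).
#'
#' @param per_class_ap numeric vector of per-class AP (NA = class absent)
#' @return mAP in `[0, 1]`
#' @export
mean_ap <- function(per_class_ap) {
  v <- per_class_ap[!is.na(per_class_ap)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Evaluate a set of detections against ground truth
#'
#' Runs the full confidence sweep per class: detections across all images
#' are sorted by decreasing confidence, matched greedily one-to-one within
#' their image, and accumulated into a precision-recall curve; AP is the
#' exact area under the precision envelope. Precision/recall/F1 are reported
#' at the confidence that maximizes F1.
#'
#' @param pred data.frame with columns image, class_id, x1, y1, x2, y2,
#'   confidence
#' @param truth data.frame with columns image, class_id, x1, y1, x2, y2
#' @param classes integer vector of class ids to evaluate
#' @param iou_threshold single IoU threshold
#' @return list with per_class data.frame (ap, precision, recall, f1,
#'   n_truth) and scalars mAP, precision, recall, f1
#' @export
evaluate_detections <- function(pred, truth, classes = sort(unique(truth$class_id)),
                                iou_threshold = 0.5) {
  per <- lapply(classes, function(cl) {
    tr <- truth[truth$class_id == cl, , drop = FALSE]
    pd <- pred[pred$class_id == cl, , drop = FALSE]
    n_truth <- nrow(tr)
    if (n_truth == 0) return(data.frame(class_id = cl, ap = NA_real_,
                                        precision = NA_real_, recall = NA_real_,
                                        f1 = NA_real_, n_truth = 0L))
    if (nrow(pd) == 0) return(data.frame(class_id = cl, ap = 0,
                                         precision = 0, recall = 0, f1 = 0,
                                         n_truth = n_truth))
    is_tp <- logical(nrow(pd))
    for (img in unique(pd$image)) {
      sel <- pd$image == img
      m <- match_detections(pd[sel, , drop = FALSE],
                            tr[tr$image == img, , drop = FALSE],
                            iou_threshold)
      is_tp[sel] <- !is.na(m$matched)
    }
    curve <- pr_curve(pd$confidence, is_tp, n_truth)
    ap <- average_precision(curve)
    fs <- ifelse(curve$precision + curve$recall > 0,
                 2 * curve$precision * curve$recall /
                   (curve$precision + curve$recall), 0)
    i <- which.max(fs)
    data.frame(class_id = cl, ap = ap, precision = curve$precision[i],
               recall = curve$recall[i], f1 = fs[i], n_truth = n_truth)
  })
  per <- do.call(rbind, per)
  ok <- !is.na(per$ap)
  list(per_class = per,
       mAP = mean_ap(per$ap),
       precision = if (any(ok)) mean(per$precision[ok]) else NA_real_,
       recall = if (any(ok)) mean(per$recall[ok]) else NA_real_,
       f1 = if (any(ok)) mean(per$f1[ok]) else NA_real_)
}

#' mAP averaged over a range of IoU thresholds
#'
#' Default thresholds 0.50, 0.55, ..., 0.95 (ten values, COCO convention).
#'
#' @inheritParams evaluate_detections
#' @param thresholds IoU thresholds to average over
#' @return mAP50-95 in `[0, 1]`
#' @export
map_range <- function(pred, truth, classes = sort(unique(truth$class_id)),
                      thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds, function(th)
    evaluate_detections(pred, truth, classes, th)$mAP, 0))
}

#' Coefficient of determination for counts
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. 1 for perfect
#' prediction, 0 for the constant-mean prediction, possibly negative.
#'
#' @param actual,predicted paired count vectors (length >= 2; the actual
#'   counts must have positive variance)
#' @return R-squared (<= 1)
#' @export
r_squared <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("actual counts have zero variance")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Classification accuracy
#'
#' For a confusion matrix (rows = truth, columns = prediction) the trace
#' over the total; for binary confusion counts,
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c a square confusion matrix, or a list with TP, TN, FP, FN
#' @return accuracy in `[0, 1]`
#' @export
accuracy <- function(c) {
  if (is.matrix(c)) return(sum(diag(c)) / sum(c))
  (c$TP + c$TN) / (c$TP + c$TN + c$FP + c$FN)
}
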