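#' Inference: decoding, non-maximum suppression, counting
#'
#' @name detect
NULL

# decode raw head tensors into a detection data.frame for each batch item
decode_heads <- function(model, heads, conf_threshold = 0.25) {
  cfg <- model$cfg
  nc <- cfg$n_classes
  per <- 5L + nc
  out <- list()
  for (s in 1:3) {
    t5 <- heads[[s]]
    d <- dim(t5)
    N <- d[1]; Hg <- d[3]; Wg <- d[4]
    stride <- cfg$strides[s]
    for (a in 1:3) {
      ch0 <- (a - 1L) * per
      sx <- sigmoid(t5[, ch0 + 1, , , drop = FALSE])
      sy <- sigmoid(t5[, ch0 + 2, , , drop = FALSE])
      sw <- sigmoid(t5[, ch0 + 3, , , drop = FALSE])
      sh <- sigmoid(t5[, ch0 + 4, , , drop = FALSE])
      ob <- sigmoid(t5[, ch0 + 5, , , drop = FALSE])
      pc <- array(0, c(N, nc, Hg, Wg))
      for (k in seq_len(nc))
        pc[, k, , ] <- sigmoid(t5[, ch0 + 5 + k, , ])
      best <- apply(pc, c(1, 3, 4), which.max)
      bestp <- apply(pc, c(1, 3, 4), max)
      conf <- array(ob, c(N, Hg, Wg)) * bestp
      keep <- which(conf >= conf_threshold, arr.ind = TRUE)
      if (nrow(keep) == 0) next
      gi <- keep[, 3] - 1; gj <- keep[, 2] - 1
      li <- cbind(keep[, 1], 1, keep[, 2], keep[, 3])
      cx <- (2 * sx[li] - 0.5 + gi) * stride
      cy <- (2 * sy[li] - 0.5 + gj) * stride
      w <- (2 * sw[li])^2 * cfg$anchors[s, a, 1]
      h <- (2 * sh[li])^2 * cfg$anchors[s, a, 2]
      out[[length(out) + 1]] <- data.frame(
        item = keep[, 1],
        class_id = best[keep] - 1,
        x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
        confidence = conf[keep])
    }
  }
  dets <- do.call(rbind, out)
  if (is.null(dets))
    dets <- data.frame(item = integer(0), class_id = numeric(0),
                       x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                       y2 = numeric(0), confidence = numeric(0))
  dets
}

#' Non-maximum suppression
#'
#' Per class: keep the highest-confidence box, suppress boxes overlapping a
#' kept box at IoU > `iou_threshold`, repeat. Survivors all have confidence
#' >= `confidence_threshold`. The output is a subset of the input and the
#' operation is idempotent.
#'
#' @param detections data.frame with columns class_id, x1, y1, x2, y2,
#'   confidence
#' @param iou_threshold suppression overlap threshold in `[0, 1]`
#' @param confidence_threshold minimum confidence in `[0, 1]`
#' @param agnostic suppress across classes (used for counting, where one
#'   flower must yield one box regardless of class confusion)
#' @return the surviving rows of `detections`
#' @export
nms <- function(detections, iou_threshold = 0.45,
                confidence_threshold = 0.25, agnostic = FALSE) {
  if (iou_threshold < 0 || iou_threshold > 1 ||
      confidence_threshold < 0 || confidence_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  if (NROW(detections) == 0) return(detections)
  det <- detections[detections$confidence >= confidence_threshold, ,
                    drop = FALSE]
  keep_rows <- integer(0)
  groups <- if (agnostic) list(unique(det$class_id)) else
    as.list(unique(det$class_id))
  for (cl in groups) {
    rows <- which(det$class_id %in% cl)
    rows <- rows[order(-det$confidence[rows])]
    boxes <- as.matrix(det[rows, c("x1", "y1", "x2", "y2")])
    alive <- rep(TRUE, length(rows))
    for (i in seq_along(rows)) {
      if (!alive[i]) next
      keep_rows <- c(keep_rows, rows[i])
      if (i < length(rows)) {
        later <- which(alive & seq_along(rows) > i)
        if (length(later)) {
          ov <- iou_matrix(boxes[i, , drop = FALSE],
                           boxes[later, , drop = FALSE])
          alive[later[ov > iou_threshold]] <- FALSE
        }
      }
    }
  }
  det[sort(keep_rows), , drop = FALSE]
}

#' Run the detector on images
#'
#' @param object a `tflos_fit` or `tflos_model`
#' @param images character vector of image paths, or a list of (H, W, 3)
#'   arrays
#' @param conf_threshold,iou_threshold decoding and NMS thresholds
#'   (defaults from the model config)
#' @param agnostic class-agnostic NMS (see [nms()])
#' @param ... unused
#' @return data.frame of detections with columns image, class_id, x1, y1,
#'   x2, y2, confidence (pixel coordinates at the model input size)
#' @export
predict.tflos_fit <- function(object, images, conf_threshold = NULL,
                              iou_threshold = NULL, agnostic = FALSE, ...) {
  model <- if (inherits(object, "tflos_fit")) object$model else object
  cfg <- model$cfg
  if (is.null(conf_threshold)) conf_threshold <- cfg$conf_threshold_count
  if (is.null(iou_threshold)) iou_threshold <- cfg$iou_threshold_nms
  nms_conf <- conf_threshold
  paths <- if (is.character(images)) images else names(images)
  res <- list()
  for (i in seq_along(images)) {
    img <- if (is.character(images)) read_image(images[i]) else images[[i]]
    nm <- if (is.character(images)) basename(images[i])
    else sprintf("image_%d", i)
    if (dim(img)[1] != cfg$input_size || dim(img)[2] != cfg$input_size)
      img <- resize_nearest(img, cfg$input_size, cfg$input_size)
    fw <- model_forward(model, image_to_tensor(img), training = FALSE)
    dets <- decode_heads(model, fw$heads, conf_threshold)
    dets <- nms(dets, iou_threshold, nms_conf, agnostic = agnostic)
    if (nrow(dets)) {
      dets$image <- nm
      res[[length(res) + 1]] <- dets[, c("image", "class_id", "x1", "y1",
                                         "x2", "y2", "confidence")]
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(image = character(0), class_id = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), confidence = numeric(0))
  out
}

#' @export
predict.tflos_model <- predict.tflos_fit

#' Detect and count flowers, writing a counting CSV
#'
#' One count record per input image (rows in input order): the number of
#' post-NMS detections per class at the counting confidence threshold.
#' Unreadable images produce an error row (NA counts) and processing
#' continues.
#'
#' @param images character vector of image paths or list of arrays
#' @param model a `tflos_fit` or `tflos_model`
#' @param conf_threshold,iou_threshold thresholds (defaults from config)
#' @param csv optional output CSV path (header
#'   `image,bud,b_flower,w_flower,total`)
#' @param dates,accessions optional per-image metadata columns
#' @return data.frame of count records
#' @export
detect_and_count <- function(images, model, conf_threshold = NULL,
                             iou_threshold = NULL, csv = NULL,
                             dates = NULL, accessions = NULL) {
  n <- length(images)
  rec <- data.frame(image = character(n), bud = NA_integer_,
                    b_flower = NA_integer_, w_flower = NA_integer_,
                    total = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    nm <- if (is.character(images)) basename(images[i])
    else sprintf("image_%d", i)
    rec$image[i] <- nm
    dets <- tryCatch(
      predict.tflos_fit(model, if (is.character(images)) images[i]
                        else images[i],
                        conf_threshold = conf_threshold,
                        iou_threshold = iou_threshold, agnostic = TRUE),
      error = function(e) {
        warning("image ", nm, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(dets)) next
    rec$bud[i] <- sum(dets$class_id == 0)
    rec$b_flower[i] <- sum(dets$class_id == 1)
    rec$w_flower[i] <- sum(dets$class_id == 2)
    rec$total[i] <- nrow(dets)
  }
  if (!is.null(dates)) rec$date <- dates
  if (!is.null(accessions)) rec$accession <- accessions
  if (!is.null(csv)) write.csv(rec, csv, row.names = FALSE)
  rec
}

#' Evaluate a trained detector on a dataset split
#'
#' Runs inference at the evaluation confidence threshold, applies NMS, and
#' scores against the split's labels: per-class AP, mAP at IoU 0.5,
#' mAP 0.5-0.95, and counting R-squared of total per-image counts at the
#' counting threshold against label counts.
#'
#' @param fit a `tflos_fit`
#' @param data_dir dataset directory
#' @param split `"train"`, `"val"` or `"test"`
#' @param map_range_too also compute mAP over the 0.50-0.95 range (slower)
#' @param count_conf counting confidence threshold (default from config;
#'   see [calibrate_counting()])
#' @param count_scale multiplicative count-calibration factor fitted on the
#'   validation split (1 = raw counts)
#' @return list with `detection` (from [evaluate_detections()]),
#'   `mAP50`, optional `mAP50_95`, and `count_r2`
#' @export
evaluate_model <- function(fit, data_dir, split = "val",
                           map_range_too = FALSE, count_conf = NULL,
                           count_scale = 1) {
  model <- if (inherits(fit, "tflos_fit")) fit$model else fit
  cfg <- model$cfg
  if (is.null(count_conf)) count_conf <- cfg$conf_threshold_count
  listing <- list_split(data_dir, split)
  if (nrow(listing) == 0) stop("no images in split ", split)
  truth <- split_truth(listing, cfg$input_size)
  pred <- predict.tflos_fit(model, listing$image,
                            conf_threshold = cfg$conf_threshold_eval)
  ev <- evaluate_detections(pred, truth, classes = 0:(cfg$n_classes - 1))
  # counting uses class-agnostic suppression (one flower, one box)
  cnt_pred <- nms(pred, cfg$iou_threshold_nms, count_conf, agnostic = TRUE)
  imgs <- basename(listing$image)
  actual <- vapply(imgs, function(im) sum(truth$image == im), 0)
  predicted <- vapply(imgs, function(im) sum(cnt_pred$image == im), 0) *
    count_scale
  r2 <- if (sd(actual) > 0) r_squared(actual, predicted) else NA_real_
  out <- list(detection = ev, mAP50 = ev$mAP, count_r2 = r2,
              per_image = data.frame(image = imgs, actual = actual,
                                     predicted = predicted))
  if (map_range_too)
    out$mAP50_95 <- map_range(pred, truth,
                              classes = 0:(cfg$n_classes - 1))
  out
}

#' Calibrate a counting estimator on a validation split
#'
#' Defines the calibrated counting estimator
#' `count = intercept + slope * n_boxes(nms_iou, threshold)` where
#' `n_boxes` is the number of class-agnostic post-NMS detections. The NMS
#' overlap, confidence threshold, and linear map are chosen to maximize
#' counting R-squared against the labeled per-image totals of the given
#' split (normally `"val"`, keeping the test split untouched). The linear
#' map plays the role of the regression between predicted and manually
#' observed counts that calibrates detector counting in field phenotyping:
#' crowded scenes inflate raw box counts roughly proportionally, so a
#' looser NMS overlap plus a linear correction is more faithful than a
#' hard threshold alone. Raw per-class CSV counts are unaffected.
#'
#' @inheritParams evaluate_model
#' @param iou_grid NMS overlap thresholds to try
#' @param thr_grid confidence thresholds to try
#' @return list(nms_iou, threshold, intercept, slope, r2, sweep)
#' @export
calibrate_counting <- function(fit, data_dir, split = "val",
                               iou_grid = c(0.45, 0.5, 0.6),
                               thr_grid = seq(0.15, 0.6, by = 0.05)) {
  model <- if (inherits(fit, "tflos_fit")) fit$model else fit
  cfg <- model$cfg
  listing <- list_split(data_dir, split)
  truth <- split_truth(listing, cfg$input_size)
  # single decode, no suppression; NMS variants are applied offline
  pred <- predict.tflos_fit(model, listing$image,
                            conf_threshold = min(thr_grid) / 2,
                            iou_threshold = 0.999)
  imgs <- basename(listing$image)
  actual <- vapply(imgs, function(im) sum(truth$image == im), 0)
  rows <- list()
  for (iou in iou_grid) {
    for (th in thr_grid) {
      # suppression exactly as deployed: threshold first, then NMS
      base <- nms(pred, iou, th, agnostic = TRUE)
      n <- vapply(imgs, function(im) sum(base$image == im), 0)
      if (sd(n) == 0 || sd(actual) == 0) next
      cf <- coef(stats::lm(actual ~ n))
      rows[[length(rows) + 1]] <- data.frame(
        nms_iou = iou, threshold = th, intercept = cf[1], slope = cf[2],
        r2 = r_squared(actual, cf[1] + cf[2] * n))
    }
  }
  sweep <- do.call(rbind, rows)
  rownames(sweep) <- NULL
  best <- sweep[which.max(sweep$r2), ]
  list(nms_iou = best$nms_iou, threshold = best$threshold,
       intercept = best$intercept, slope = best$slope, r2 = best$r2,
       sweep = sweep)
}

#' Apply a calibrated counting estimator to a dataset split
#'
#' @param fit a `tflos_fit`
#' @param data_dir dataset directory
#' @param split split to count on
#' @param counter calibration from [calibrate_counting()]
#' @return data.frame with per-image actual and calibrated predicted
#'   counts, with the split R-squared as attribute `"r2"`
#' @export
count_with_calibration <- function(fit, data_dir, split, counter) {
  model <- if (inherits(fit, "tflos_fit")) fit$model else fit
  cfg <- model$cfg
  listing <- list_split(data_dir, split)
  truth <- split_truth(listing, cfg$input_size)
  # exactly the calibration pipeline: decode with near-duplicate removal
  # (IoU > 0.999), then agnostic NMS at the calibrated overlap/threshold
  pred <- predict.tflos_fit(model, listing$image,
                            conf_threshold = counter$threshold,
                            iou_threshold = 0.999)
  pred <- nms(pred, counter$nms_iou, counter$threshold, agnostic = TRUE)
  imgs <- basename(listing$image)
  actual <- vapply(imgs, function(im) sum(truth$image == im), 0)
  n <- vapply(imgs, function(im) sum(pred$image == im), 0)
  predicted <- counter$intercept + counter$slope * n
  out <- data.frame(image = imgs, actual = actual, boxes = n,
                    predicted = predicted)
  attr(out, "r2") <- if (sd(actual) > 0) r_squared(actual, predicted)
  else NA_real_
  out
}
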