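# Box geometry. Pixel boxes are 0-based, half-open [x1, x2) x [y1, y2) with
# origin at the top-left; label-file boxes are centre-normalized (cx cy w h).

#' Convert normalized centre boxes to pixel corner boxes
#'
#' @param boxes matrix or data.frame with columns cx, cy, w, h in `[0,1]`
#' @param width,height image size in pixels
#' @return matrix with columns x1, y1, x2, y2 (pixels, half-open)
#' @export
xywhn_to_xyxy <- function(boxes, width, height) {
  b <- as.matrix(boxes)
  out <- cbind(x1 = (b[, 1] - b[, 3] / 2) * width,
               y1 = (b[, 2] - b[, 4] / 2) * height,
               x2 = (b[, 1] + b[, 3] / 2) * width,
               y2 = (b[, 2] + b[, 4] / 2) * height)
  out
}

#' Convert pixel corner boxes to normalized centre boxes
#'
#' @param boxes matrix with columns x1, y1, x2, y2 in pixels
#' @param width,height image size in pixels
#' @return matrix with columns cx, cy, w, h in `[0,1]`
#' @export
xyxy_to_xywhn <- function(boxes, width, height) {
  b <- as.matrix(boxes)
  cbind(cx = (b[, 1] + b[, 3]) / 2 / width,
        cy = (b[, 2] + b[, 4]) / 2 / height,
        w = (b[, 3] - b[, 1]) / width,
        h = (b[, 4] - b[, 2]) / height)
}

#' Intersection over union of two boxes
#'
#' `area(A intersect B) / area(A union B)` for corner-format boxes. Symmetric,
#' 0 for disjoint boxes, 1 for identical boxes.
#'
#' @param box_a,box_b length-4 vectors (x1, y1, x2, y2)
#' @return a number in `[0, 1]`
#' @export
iou <- function(box_a, box_b) {
  if (box_a[3] <= box_a[1] || box_a[4] <= box_a[2] ||
      box_b[3] <= box_b[1] || box_b[4] <= box_b[2])
    stop("boxes must have positive width and height")
  iw <- min(box_a[3], box_b[3]) - max(box_a[1], box_b[1])
  ih <- min(box_a[4], box_b[4]) - max(box_a[2], box_b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  ua <- (box_a[3] - box_a[1]) * (box_a[4] - box_a[2]) +
    (box_b[3] - box_b[1]) * (box_b[4] - box_b[2]) - inter
  inter / ua
}

# IoU of each row of A against each row of B; matrices of corner boxes
iou_matrix <- function(A, B) {
  A <- matrix(A, ncol = 4); B <- matrix(B, ncol = 4)
  n <- nrow(A); m <- nrow(B)
  iw <- pmin(matrix(A[, 3], n, m), matrix(B[, 3], n, m, byrow = TRUE)) -
    pmax(matrix(A[, 1], n, m), matrix(B[, 1], n, m, byrow = TRUE))
  ih <- pmin(matrix(A[, 4], n, m), matrix(B[, 4], n, m, byrow = TRUE)) -
    pmax(matrix(A[, 2], n, m), matrix(B[, 2], n, m, byrow = TRUE))
  inter <- pmax(iw, 0) * pmax(ih, 0)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (matrix(areaA, n, m) + matrix(areaB, n, m, byrow = TRUE) - inter)
}

#' Tile an image into 2 x 2 quadrants with label bookkeeping
#'
#' Splits an image into four equal non-overlapping quadrants in row-major
#' order (top-left, top-right, bottom-left, bottom-right) and re-normalizes
#' box labels per tile. Boxes straddling a cut are clipped; clipped fragments
#' whose visible area fraction (relative to the original box) falls below
#' `min_visible_fraction` are dropped.
#'
#' @param image an (H, W, 3) array, or NULL to tile labels only
#' @param boxes optional matrix/data.frame with columns class, cx, cy, w, h
#'   (normalized)
#' @param width,height full-image pixel size (taken from `image` when given)
#' @param min_visible_fraction drop threshold for clipped fragments
#'   (0 keeps every fragment with positive area)
#' @param expected_size optional c(width, height); when the input does not
#'   match, `on_size_mismatch` selects `"fail"` (default) or `"resize"`
#'   (nearest-neighbour)
#' @param on_size_mismatch see `expected_size`
#' @return list of four tiles, each `list(image, boxes)` with normalized
#'   per-tile boxes
#' @export
tile_image <- function(image = NULL, boxes = NULL, width = NULL,
                       height = NULL, min_visible_fraction = 0.25,
                       expected_size = NULL,
                       on_size_mismatch = c("fail", "resize")) {
  on_size_mismatch <- match.arg(on_size_mismatch)
  if (!is.null(image)) {
    height <- dim(image)[1]; width <- dim(image)[2]
  }
  if (is.null(width) || is.null(height))
    stop("provide an image or explicit width/height")
  if (!is.null(expected_size) &&
      (width != expected_size[1] || height != expected_size[2])) {
    if (on_size_mismatch == "fail")
      stop(sprintf("input is %dx%d, expected %dx%d", width, height,
                   expected_size[1], expected_size[2]))
    image <- resize_nearest(image, expected_size[2], expected_size[1])
    height <- expected_size[2]; width <- expected_size[1]
  }
  tw <- width / 2; th <- height / 2
  bx <- if (is.null(boxes) || NROW(boxes) == 0) NULL else as.matrix(boxes)
  tiles <- vector("list", 4)
  q <- 0
  for (row in 0:1) for (col in 0:1) {
    q <- q + 1
    x0 <- col * tw; y0 <- row * th
    timg <- if (!is.null(image))
      image[y0 + seq_len(th), x0 + seq_len(tw), , drop = FALSE] else NULL
    tb <- NULL
    if (!is.null(bx)) {
      px <- xywhn_to_xyxy(bx[, 2:5, drop = FALSE], width, height)
      area0 <- (px[, 3] - px[, 1]) * (px[, 4] - px[, 2])
      cx1 <- pmax(px[, 1], x0); cy1 <- pmax(px[, 2], y0)
      cx2 <- pmin(px[, 3], x0 + tw); cy2 <- pmin(px[, 4], y0 + th)
      vis <- pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0) / area0
      keep <- vis > 0 & vis >= min_visible_fraction
      if (any(keep)) {
        cl <- bx[keep, 1]
        nb <- xyxy_to_xywhn(cbind(cx1, cy1, cx2, cy2)[keep, , drop = FALSE] -
                              matrix(c(x0, y0, x0, y0), sum(keep), 4,
                                     byrow = TRUE), tw, th)
        tb <- cbind(class = cl, nb)
      }
    }
    tiles[[q]] <- list(image = timg, boxes = tb)
  }
  tiles
}

resize_nearest <- function(image, out_h, out_w) {
  d <- dim(image)
  ri <- pmin(d[1], pmax(1, round((seq_len(out_h) - 0.5) * d[1] / out_h + 0.5)))
  ci <- pmin(d[2], pmax(1, round((seq_len(out_w) - 0.5) * d[2] / out_w + 0.5)))
  image[ri, ci, , drop = FALSE]
}
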