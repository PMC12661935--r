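# Training-time augmentations. Each transform keeps image and labels
# consistent: every transformed box still covers its object.

#' Augmentation transforms
#'
#' Horizontal flip, HSV jitter (hue/saturation/value gains; labels
#' unchanged), 90-degree rotation, and four-image mosaic composition.
#'
#' @param image (H, W, 3) array in `[0, 1]`
#' @param boxes matrix with columns class, cx, cy, w, h (normalized)
#' @return list(image, boxes)
#' @name augment
NULL

#' @rdname augment
#' @export
augment_flip <- function(image, boxes = NULL) {
  image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  if (NROW(boxes) > 0) boxes[, 2] <- 1 - boxes[, 2]
  list(image = image, boxes = boxes)
}

#' @rdname augment
#' @param h_gain,s_gain,v_gain multiplicative jitter half-ranges (the
#'   standard 0.015 / 0.7 / 0.4)
#' @export
augment_hsv <- function(image, boxes = NULL, h_gain = 0.015, s_gain = 0.7,
                        v_gain = 0.4) {
  d <- dim(image)
  m <- matrix(image, d[1] * d[2], 3)
  hsvm <- rgb2hsv(t(m), maxColorValue = 1)
  g <- 1 + runif(3, -1, 1) * c(h_gain, s_gain, v_gain)
  hsvm[1, ] <- (hsvm[1, ] * g[1]) %% 1
  hsvm[2, ] <- pmin(hsvm[2, ] * g[2], 1)
  hsvm[3, ] <- pmin(hsvm[3, ] * g[3], 1)
  cols <- hsv(hsvm[1, ], hsvm[2, ], hsvm[3, ])
  rgbm <- t(grDevices::col2rgb(cols)) / 255
  list(image = array(rgbm, d), boxes = boxes)
}

#' @rdname augment
#' @export
augment_rot90 <- function(image, boxes = NULL) {
  # 90 degrees clockwise: (row, col) -> (col, H - row + 1)
  d <- dim(image)
  out <- array(0, c(d[2], d[1], d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- t(image[rev(seq_len(d[1])), , ch])
  if (NROW(boxes) > 0) {
    cx <- boxes[, 2]; cy <- boxes[, 3]
    boxes[, 2] <- 1 - cy
    boxes[, 3] <- cx
    tmp <- boxes[, 4]; boxes[, 4] <- boxes[, 5]; boxes[, 5] <- tmp
  }
  list(image = out, boxes = boxes)
}

#' @rdname augment
#' @param scenes list of four list(image, boxes) entries, equal sizes
#' @export
augment_mosaic <- function(scenes) {
  stopifnot(length(scenes) == 4)
  d <- dim(scenes[[1]]$image)
  H <- d[1]; W <- d[2]
  out <- array(0, c(H, W, 3))
  boxes <- NULL
  q <- 0
  for (row in 0:1) for (col in 0:1) {
    q <- q + 1
    sc <- scenes[[q]]
    half <- resize_nearest(sc$image, H %/% 2, W %/% 2)
    out[row * (H %/% 2) + seq_len(H %/% 2),
        col * (W %/% 2) + seq_len(W %/% 2), ] <- half
    if (NROW(sc$boxes) > 0) {
      b <- sc$boxes
      b[, 2] <- b[, 2] / 2 + col / 2
      b[, 3] <- b[, 3] / 2 + row / 2
      b[, 4] <- b[, 4] / 2
      b[, 5] <- b[, 5] / 2
      boxes <- rbind(boxes, b)
    }
  }
  list(image = out, boxes = boxes)
}
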