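#' Plain-text label and image input/output
#'
#' Labels use the standard one-line-per-object text format
#' `class_id cx cy w h` with coordinates normalized to the image size,
#' written as 6-decimal fixed point so that read -> write -> read is
#' byte-stable. Images are PNG arrays in `[0, 1]`.
#'
#' @name yolo_io
NULL

#' Read a label file
#'
#' @param path label file path
#' @return matrix with columns class, cx, cy, w, h (0 rows if empty/missing)
#' @export
read_labels <- function(path) {
  empty <- matrix(numeric(0), 0, 5,
                  dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  colnames(m) <- c("class", "cx", "cy", "w", "h")
  m
}

#' Write a label file
#'
#' @param boxes matrix/data.frame with columns class, cx, cy, w, h
#' @param path output path
#' @export
write_labels <- function(boxes, path) {
  if (is.null(boxes) || NROW(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  b <- as.matrix(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   as.integer(b[, 1]), b[, 2], b[, 3], b[, 4], b[, 5])
  writeLines(lines, path)
  invisible(path)
}

#' Read an image into an (H, W, 3) array in `[0, 1]`
#'
#' @param path PNG file path
#' @return numeric array (H, W, 3)
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an (H, W, 3) array in `[0, 1]` as PNG
#'
#' @param image numeric array
#' @param path output path
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# (H, W, 3) [0,1] image -> (1, 3, H, W) feature map
image_to_tensor <- function(image) {
  d <- dim(image)
  aperm(array(image, c(1, d[1], d[2], d[3])), c(1, 4, 2, 3))
}

# list dataset images/labels for one split of an images/ + labels/ layout
list_split <- function(dir, split) {
  img_dir <- file.path(dir, "images", split)
  lab_dir <- file.path(dir, "labels", split)
  imgs <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  labs <- file.path(lab_dir, sub("\\.png$", ".txt", basename(imgs)))
  data.frame(image = imgs, label = labs, stringsAsFactors = FALSE)
}

# ground-truth data.frame (image, class_id, x1..y2) from a split listing
split_truth <- function(listing, image_size) {
  out <- lapply(seq_len(nrow(listing)), function(i) {
    b <- read_labels(listing$label[i])
    if (nrow(b) == 0) return(NULL)
    px <- xywhn_to_xyxy(b[, 2:5, drop = FALSE], image_size, image_size)
    data.frame(image = basename(listing$image[i]), class_id = b[, 1],
               x1 = px[, 1], y1 = px[, 2], x2 = px[, 3], y2 = px[, 4])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(image = character(0), class_id = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0))
  out
}
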