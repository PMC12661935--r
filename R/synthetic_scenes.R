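#' Synthetic tea-flower scenes
#'
#' Seeded generator for desk-scale detector benchmarks. Scenes emulate the
#' documented challenges of field imagery of tea plants: dense small targets
#' on cluttered green foliage, partial occlusion by leaf/branch primitives,
#' front/back lighting and bright light-spot artifacts, with the three
#' phenological classes bud (0), blooming flower (1) and withered flower (2)
#' at a configurable prevalence (default 57/25/18%). Appearance is stylized,
#' not photorealistic: buds are small pale ellipses, blooming flowers white
#' petal rosettes with a yellow core, withered flowers brown irregular blobs.
#'
#' @param image_size square image size in pixels (default 640)
#' @param n_objects number of objects per scene; a single integer or a
#'   c(min, max) range sampled per image
#' @param class_mix probabilities for (bud, blooming, withered); must sum
#'   to 1
#' @param occlusion_rate fraction of objects partially covered by a leaf or
#'   branch primitive painted after the flowers
#' @param lighting `"frontlight"` or `"backlight"` (backlight darkens to
#'   60% brightness and reduces contrast)
#' @param light_spot_rate fraction of images receiving 1-3 bright elliptical
#'   artifacts at opacity 0.5
#' @param min_visible_fraction objects whose own-mask visible fraction after
#'   occlusion painting falls below this are not labeled
#' @param size_scale multiplier on object sizes (sizes are defined at the
#'   640-px reference scale and scale with `image_size`)
#' @param seed integer seed; the same spec is bit-reproducible
#' @return a `scene_spec` list
#' @export
scene_spec <- function(image_size = 640, n_objects = 12,
                       class_mix = c(0.57, 0.25, 0.18),
                       occlusion_rate = 0.3,
                       lighting = c("frontlight", "backlight"),
                       light_spot_rate = 0.2,
                       min_visible_fraction = 0.25,
                       size_scale = 1,
                       seed = 0L) {
  lighting <- match.arg(lighting)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (min_visible_fraction <= 0 || min_visible_fraction > 1)
    stop("min_visible_fraction must be in (0, 1]")
  if (length(n_objects) == 1) n_objects <- c(n_objects, n_objects)
  structure(list(image_size = as.integer(image_size),
                 n_objects = as.integer(n_objects),
                 class_mix = class_mix,
                 occlusion_rate = occlusion_rate,
                 lighting = lighting,
                 light_spot_rate = light_spot_rate,
                 min_visible_fraction = min_visible_fraction,
                 size_scale = size_scale,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Easy benchmark scenes
#'
#' A documented easy preset used by the scaled-down learning benchmarks:
#' fewer, larger, unoccluded objects with no lighting artifacts, so that a
#' tiny detector can be trained quickly on commodity hardware.
#'
#' @inheritParams scene_spec
#' @export
easy_scene_spec <- function(image_size = 160, n_objects = c(1, 12),
                            class_mix = c(0.4, 0.35, 0.25), seed = 0L) {
  scene_spec(image_size = image_size, n_objects = n_objects,
             class_mix = class_mix, occlusion_rate = 0,
             light_spot_rate = 0, size_scale = 4, seed = seed)
}

# --- drawing primitives -------------------------------------------------

# paint a filled rotated ellipse; returns list(image, mask_idx)
paint_ellipse <- function(img, cy, cx, ry, rx, angle, col, alpha = 1) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(ry, rx)
  y0 <- max(1, floor(cy - r)); y1 <- min(H, ceiling(cy + r))
  x0 <- max(1, floor(cx - r)); x1 <- min(W, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(list(image = img, idx = integer(0)))
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  ca <- cos(angle); sa <- sin(angle)
  u <- (dy * ca + dx * sa) / ry
  v <- (-dy * sa + dx * ca) / rx
  inside <- u * u + v * v <= 1
  if (!any(inside)) return(list(image = img, idx = integer(0)))
  sub <- which(inside, arr.ind = TRUE)
  lin <- (ys[sub[, 1]]) + (xs[sub[, 2]] - 1) * H  # 1-based linear (H,W)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[lin] <- (1 - alpha) * plane[lin] + alpha * col[ch]
    img[, , ch] <- plane
  }
  list(image = img, idx = lin)
}

# thick line segment (branch stroke)
paint_stroke <- function(img, y1, x1, y2, x2, thick, col, alpha = 1) {
  n <- max(2, ceiling(sqrt((y2 - y1)^2 + (x2 - x1)^2)))
  t <- seq(0, 1, length.out = n)
  idx <- integer(0)
  for (i in seq_len(n)) {
    r <- paint_ellipse(img, y1 + t[i] * (y2 - y1), x1 + t[i] * (x2 - x1),
                       thick, thick, 0, col, alpha)
    img <- r$image
    idx <- c(idx, r$idx)
  }
  list(image = img, idx = unique(idx))
}

draw_object <- function(img, class_id, cy, cx, size) {
  if (class_id == 0) {                   # bud: pale pinkish ellipse
    r <- paint_ellipse(img, cy, cx, size / 2, size / 2.8,
                       runif(1, 0, pi), c(0.93, 0.82, 0.80))
    idx <- r$idx; img <- r$image
  } else if (class_id == 1) {            # blooming: white rosette + core
    idx <- integer(0)
    np <- sample(5:7, 1)
    for (p in seq_len(np)) {
      ang <- 2 * pi * p / np + runif(1, -0.2, 0.2)
      r <- paint_ellipse(img, cy + sin(ang) * size / 4.5,
                         cx + cos(ang) * size / 4.5,
                         size / 3.4, size / 5.5, ang,
                         c(0.97, 0.97, 0.93))
      img <- r$image; idx <- c(idx, r$idx)
    }
    r <- paint_ellipse(img, cy, cx, size / 5.5, size / 5.5, 0,
                       c(0.95, 0.82, 0.25))
    img <- r$image; idx <- unique(c(idx, r$idx))
  } else {                               # withered: brown irregular blob
    idx <- integer(0)
    for (p in 1:3) {
      r <- paint_ellipse(img, cy + runif(1, -size / 6, size / 6),
                         cx + runif(1, -size / 6, size / 6),
                         size / 3 * runif(1, 0.7, 1.1),
                         size / 3 * runif(1, 0.5, 1), runif(1, 0, pi),
                         c(0.45, 0.31, 0.16) * runif(1, 0.85, 1.15))
      img <- r$image; idx <- c(idx, r$idx)
    }
    idx <- unique(idx)
  }
  list(image = img, idx = idx)
}

scene_background <- function(n) {
  img <- array(0, c(n, n, 3))
  base <- c(0.13, 0.30, 0.10)
  for (ch in 1:3) img[, , ch] <- base[ch] + rnorm(n * n, sd = 0.02)
  for (i in seq_len(max(6, n %/% 50))) {   # layered foliage ellipses
    col <- c(0.10, 0.25, 0.08) * runif(1, 0.6, 1.6)
    img <- paint_ellipse(img, runif(1, 0, n), runif(1, 0, n),
                         runif(1, n / 12, n / 4), runif(1, n / 12, n / 4),
                         runif(1, 0, pi), pmin(col, 1), 0.7)$image
  }
  for (i in seq_len(max(2, n %/% 120))) {  # dark branch strokes
    img <- paint_stroke(img, runif(1, 0, n), runif(1, 0, n),
                        runif(1, 0, n), runif(1, 0, n),
                        max(1, n / 300), c(0.15, 0.10, 0.05), 0.9)$image
  }
  img
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic scene
#'
#' Paints a background, places the requested objects (rejecting placements
#' that overlap an existing object box at IoU > 0.5; a bounded number of
#' attempts, after which a placement-failure error is raised), paints
#' occluder primitives over a fraction of objects, applies the lighting
#' model and light spots, and emits normalized labels. Objects whose own
#' mask is occluded below `min_visible_fraction` are left unlabeled; the
#' manifest counts record the true pre-occlusion class counts.
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (H, W, 3 array), `boxes` (matrix class, cx,
#'   cy, w, h; 0 rows when empty) and `counts_true` (bud, bloom, wither)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n <- spec$image_size
    img <- scene_background(n)
    n_obj <- if (spec$n_objects[1] == spec$n_objects[2]) spec$n_objects[1]
    else sample(spec$n_objects[1]:spec$n_objects[2], 1)
    size_lo <- c(8, 15, 10) * n / 640 * spec$size_scale
    size_hi <- c(20, 40, 30) * n / 640 * spec$size_scale
    counts_true <- c(bud = 0L, bloom = 0L, wither = 0L)
    objs <- list()
    placed <- NULL
    attempts <- 0L
    max_attempts <- 60L * max(n_obj, 1L)
    while (length(objs) < n_obj) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("placement failure: could not place ", n_obj,
             " objects without degenerate overlap")
      cls <- sample(0:2, 1, prob = spec$class_mix)
      size <- min(runif(1, size_lo[cls + 1], size_hi[cls + 1]), 0.9 * n)
      cy <- runif(1, size / 2 + 1, n - size / 2 - 1)
      cx <- runif(1, size / 2 + 1, n - size / 2 - 1)
      cand <- c(cx - size / 2, cy - size / 2, cx + size / 2, cy + size / 2)
      if (!is.null(placed) && nrow(placed) > 0) {
        # degenerate placements: heavy mutual overlap, or one box mostly
        # swallowed by another (IoU alone cannot catch nesting)
        iw <- pmax(pmin(cand[3], placed[, 3]) - pmax(cand[1], placed[, 1]), 0)
        ih <- pmax(pmin(cand[4], placed[, 4]) - pmax(cand[2], placed[, 2]), 0)
        inter <- iw * ih
        a_cand <- (cand[3] - cand[1]) * (cand[4] - cand[2])
        a_pl <- (placed[, 3] - placed[, 1]) * (placed[, 4] - placed[, 2])
        iou_v <- inter / (a_cand + a_pl - inter)
        contain <- inter / pmin(a_cand, a_pl)
        if (max(iou_v) > 0.5 || max(contain) > 0.7) next
      }
      placed <- rbind(placed, cand)
      objs[[length(objs) + 1]] <- list(class = cls, cy = cy, cx = cx,
                                       size = size)
    }
    # paint flowers and keep each object's own mask
    for (i in seq_along(objs)) {
      o <- objs[[i]]
      r <- draw_object(img, o$class, o$cy, o$cx, o$size)
      img <- r$image
      objs[[i]]$idx <- r$idx
      counts_true[o$class + 1] <- counts_true[o$class + 1] + 1L
    }
    # occluders painted after the flowers
    occluded_idx <- integer(0)
    if (spec$occlusion_rate > 0 && length(objs) > 0) {
      n_occ <- rbinom(1, length(objs), spec$occlusion_rate)
      for (i in utils::head(sample(seq_along(objs)), n_occ)) {
        o <- objs[[i]]
        if (runif(1) < 0.5) {            # leaf
          r <- paint_ellipse(img, o$cy + runif(1, -o$size / 3, o$size / 3),
                             o$cx + runif(1, -o$size / 3, o$size / 3),
                             o$size * 0.7, o$size * 0.4, runif(1, 0, pi),
                             c(0.12, 0.28, 0.09))
        } else {                         # branch
          ang <- runif(1, 0, pi)
          r <- paint_stroke(img,
                            o$cy - sin(ang) * o$size, o$cx - cos(ang) * o$size,
                            o$cy + sin(ang) * o$size, o$cx + cos(ang) * o$size,
                            max(1, o$size / 6), c(0.16, 0.11, 0.05))
        }
        img <- r$image
        occluded_idx <- c(occluded_idx, r$idx)
      }
      occluded_idx <- unique(occluded_idx)
    }
    # lighting
    if (spec$lighting == "backlight") {
      m <- mean(img)
      img <- (img * 0.6 - m * 0.6) * 0.7 + m * 0.6
    }
    if (spec$light_spot_rate > 0 && runif(1) < spec$light_spot_rate) {
      for (i in seq_len(sample(1:3, 1)))
        img <- paint_ellipse(img, runif(1, 0, n), runif(1, 0, n),
                             runif(1, n / 20, n / 6), runif(1, n / 20, n / 6),
                             runif(1, 0, pi), c(1, 1, 1), 0.5)$image
    }
    img <- pmin(pmax(img, 0), 1)
    # labels from visible masks
    boxes <- NULL
    for (o in objs) {
      if (!length(o$idx)) next
      vis <- if (length(occluded_idx)) 1 - mean(o$idx %in% occluded_idx) else 1
      if (vis < spec$min_visible_fraction) next
      rows <- ((o$idx - 1) %% n) + 1
      cols <- ((o$idx - 1) %/% n) + 1
      boxes <- rbind(boxes, c(o$class,
                              (min(cols) - 1 + max(cols)) / 2 / n,
                              (min(rows) - 1 + max(rows)) / 2 / n,
                              (max(cols) - min(cols) + 1) / n,
                              (max(rows) - min(rows) + 1) / n))
    }
    if (is.null(boxes))
      boxes <- matrix(numeric(0), 0, 5)
    colnames(boxes) <- c("class", "cx", "cy", "w", "h")
    list(image = img, boxes = boxes, counts_true = counts_true)
  })
}

# largest-remainder split of n into integer parts proportional to fractions
split_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a dataset directory in the standard detection layout
#'
#' Writes `images/{train,val,test}/*.png` and matching
#' `labels/{train,val,test}/*.txt`, plus a `manifest.csv` with the true
#' pre-occlusion class counts per image. Image i is generated from the base
#' spec with seed `spec$seed + i`, so the dataset is reproducible
#' image-by-image. Split sizes use largest-remainder rounding of the
#' requested fractions.
#'
#' @param spec a [scene_spec()]
#' @param n_images total number of images
#' @param dir output directory
#' @param split fractions for (train, val, test); must sum to 1
#' @return the dataset directory, invisibly; the manifest as attribute
#'   `"manifest"`
#' @export
generate_dataset <- function(spec, n_images, dir,
                             split = c(0.6, 0.2, 0.2)) {
  stopifnot(inherits(spec, "scene_spec"))
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  counts <- split_counts(n_images, split)
  splits <- rep(c("train", "val", "test"), counts)
  for (s in unique(splits)) {
    dir.create(file.path(dir, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  manifest <- data.frame(image = character(n_images), split = splits,
                         n_bud = 0L, n_bloom = 0L, n_wither = 0L,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- spec$seed + i
    sc <- generate_scene(sp)
    nm <- sprintf("img_%05d", i)
    write_image(sc$image, file.path(dir, "images", splits[i],
                                    paste0(nm, ".png")))
    write_labels(sc$boxes, file.path(dir, "labels", splits[i],
                                     paste0(nm, ".txt")))
    manifest$image[i] <- paste0(nm, ".png")
    manifest[i, c("n_bud", "n_bloom", "n_wither")] <- as.list(sc$counts_true)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(structure(dir, manifest = manifest))
}
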