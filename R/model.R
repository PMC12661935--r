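#' Detector model configuration
#'
#' Width/depth-scalable single-stage detector: CSPDarknet-style backbone
#' (stem + four stages of strided conv and C3 blocks + SPPF), squeeze-and-
#' excitation attached after the deepest strided convolution (backbone layer
#' 7 in 0-based order), optional adaptive rectangular convolution inside the
#' C3 bottlenecks of backbone stages 2 and 3, an optional CAAFT block on the
#' deep path before the neck, a PANet-style feature-fusion neck, and three
#' detection heads at strides 8/16/32 (grids 80/40/20 at 640 px input),
#' each predicting 3 anchors x (5 + n_classes) channels.
#'
#' @param input_size square input size in pixels, divisible by 32
#' @param n_classes number of object classes (3: bud, blooming, withered)
#' @param depth_multiple,width_multiple scaling of block repeats and channel
#'   widths (defaults are the medium-scale 0.67 / 0.75)
#' @param se_layer_index 0-based backbone layer the SE block follows
#' @param use_se,use_caaft enable the attention blocks
#' @param arconv_stages backbone stages (2 and/or 3) whose C3 bottlenecks
#'   use adaptive rectangular convolution; empty vector disables it
#' @param caaft_placement `"backbone_end"` (after SPPF, before the neck)
#' @param anchors 3 x 3 x 2 array of anchor (w, h) pairs in pixels, one set
#'   of three per detection scale; defaults are the standard COCO anchors
#' @param strides detection strides, fixed at (8, 16, 32)
#' @param arconv_a,arconv_b,arconv_subnet_width adaptive-convolution scale
#'   factors and subnet width
#' @param conf_threshold_count,conf_threshold_eval,iou_threshold_nms
#'   detection thresholds for counting and evaluation, and the NMS overlap
#'   threshold
#' @return a `tflos_config` list
#' @export
model_config <- function(input_size = 640, n_classes = 3,
                         depth_multiple = 0.67, width_multiple = 0.75,
                         se_layer_index = 7, use_se = TRUE,
                         use_caaft = TRUE, arconv_stages = c(2, 3),
                         caaft_placement = "backbone_end",
                         anchors = default_anchors(),
                         strides = c(8, 16, 32),
                         arconv_a = 6, arconv_b = 1,
                         arconv_subnet_width = 8,
                         conf_threshold_count = 0.25,
                         conf_threshold_eval = 0.001,
                         iou_threshold_nms = 0.45) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 se_layer_index = se_layer_index,
                 use_se = use_se, use_caaft = use_caaft,
                 arconv_stages = arconv_stages,
                 caaft_placement = caaft_placement,
                 anchors = anchors, strides = strides,
                 arconv_a = arconv_a, arconv_b = arconv_b,
                 arconv_subnet_width = arconv_subnet_width,
                 conf_threshold_count = conf_threshold_count,
                 conf_threshold_eval = conf_threshold_eval,
                 iou_threshold_nms = iou_threshold_nms),
            class = "tflos_config")
}

#' @rdname model_config
#' @export
default_anchors <- function() {
  a <- array(0, c(3, 3, 2))
  a[1, , ] <- matrix(c(10, 13, 16, 30, 33, 23), 3, 2, byrow = TRUE)
  a[2, , ] <- matrix(c(30, 61, 62, 45, 59, 119), 3, 2, byrow = TRUE)
  a[3, , ] <- matrix(c(116, 90, 156, 198, 373, 326), 3, 2, byrow = TRUE)
  a
}

#' Estimate anchors from training labels by k-means
#'
#' Clusters label (w, h) pairs in pixels into 9 anchors and assigns them to
#' the three scales by increasing area.
#'
#' @param wh matrix of label widths/heights in pixels
#' @param seed RNG seed for the clustering
#' @return 3 x 3 x 2 anchor array
#' @export
anchors_from_labels <- function(wh, seed = 0) {
  wh <- matrix(wh, ncol = 2)
  wh <- wh[wh[, 1] > 0 & wh[, 2] > 0, , drop = FALSE]
  k <- min(9, nrow(wh))
  cen <- with_seed(seed, {
    if (nrow(wh) <= 9) wh else stats::kmeans(wh, 9, nstart = 5)$centers
  })
  cen <- cen[order(cen[, 1] * cen[, 2]), , drop = FALSE]
  # pad by repeating if fewer than 9 distinct boxes
  while (nrow(cen) < 9) cen <- rbind(cen, cen[nrow(cen), ])
  a <- array(0, c(3, 3, 2))
  for (s in 1:3) a[s, , ] <- cen[(s - 1) * 3 + 1:3, ]
  a
}

make_div2 <- function(x) max(2L, as.integer(2 * round(x / 2)))

#' Build the detector
#'
#' Assembles the computation graph described in [model_config()]. A forward
#' pass on a `(N, 3, input_size, input_size)` tensor yields three head
#' outputs with grids `input_size / (8, 16, 32)`, each with
#' `3 * (5 + n_classes)` channels.
#'
#' @param cfg a [model_config()]
#' @param seed seed for weight initialization
#' @return a `tflos_model` object
#' @export
build_model <- function(cfg = model_config(), seed = 0) {
  stopifnot(inherits(cfg, "tflos_config"))
  with_seed(seed, {
    wm <- cfg$width_multiple; dm <- cfg$depth_multiple
    cw <- vapply(c(64, 128, 256, 512, 1024) * wm, make_div2, 0L)
    dn <- function(n) max(1L, as.integer(round(n * dm)))
    no <- 3L * (5L + cfg$n_classes)
    ar_opts <- list(a = cfg$arconv_a, b = cfg$arconv_b,
                    subnet_width = cfg$arconv_subnet_width)
    nodes <- list()
    add <- function(op, from, unit = NULL, tag = NULL, head_scale = NULL) {
      nodes[[length(nodes) + 1]] <<- list(op = op, from = from, unit = unit,
                                          tag = tag, head_scale = head_scale)
      length(nodes)
    }
    # backbone (from = 0 means the input image)
    i0 <- add("unit", 0L, init_cbs(3L, cw[1], 3, 2), tag = "layer0")
    i1 <- add("unit", i0, init_cbs(cw[1], cw[2], 3, 2))
    i2 <- add("unit", i1, init_c3(cw[2], cw[2], dn(3)))
    i3 <- add("unit", i2, init_cbs(cw[2], cw[3], 3, 2))
    i4 <- add("unit", i3, init_c3(cw[3], cw[3], dn(6),
                                  use_arconv = 2 %in% cfg$arconv_stages,
                                  arconv_opts = ar_opts))
    i5 <- add("unit", i4, init_cbs(cw[3], cw[4], 3, 2))
    i6 <- add("unit", i5, init_c3(cw[4], cw[4], dn(9),
                                  use_arconv = 3 %in% cfg$arconv_stages,
                                  arconv_opts = ar_opts))
    i7 <- add("unit", i6, init_cbs(cw[4], cw[5], 3, 2), tag = "layer7")
    last <- i7
    if (cfg$use_se) last <- add("unit", last, init_se(cw[5]), tag = "se")
    i8 <- add("unit", last, init_c3(cw[5], cw[5], dn(3)))
    i9 <- add("unit", i8, init_sppf(cw[5], cw[5]))
    deep <- i9
    if (cfg$use_caaft) deep <- add("unit", deep, init_caaft(cw[5]),
                                   tag = "caaft")
    # neck (PANet)
    n10 <- add("unit", deep, init_cbs(cw[5], cw[4], 1))
    n11 <- add("upsample", n10)
    n12 <- add("concat", c(n11, i6))
    n13 <- add("unit", n12, init_c3(2L * cw[4], cw[4], dn(3), shortcut = FALSE))
    n14 <- add("unit", n13, init_cbs(cw[4], cw[3], 1))
    n15 <- add("upsample", n14)
    n16 <- add("concat", c(n15, i4))
    p3 <- add("unit", n16, init_c3(2L * cw[3], cw[3], dn(3), shortcut = FALSE))
    n18 <- add("unit", p3, init_cbs(cw[3], cw[3], 3, 2))
    n19 <- add("concat", c(n18, n14))
    p4 <- add("unit", n19, init_c3(2L * cw[3], cw[4], dn(3), shortcut = FALSE))
    n21 <- add("unit", p4, init_cbs(cw[4], cw[4], 3, 2))
    n22 <- add("concat", c(n21, n10))
    p5 <- add("unit", n22, init_c3(2L * cw[4], cw[5], dn(3), shortcut = FALSE))
    # heads: plain 1x1 convolutions with the standard focal-style bias init
    for (s in 1:3) {
      bias <- rep(0, no)
      per <- 5L + cfg$n_classes
      for (a in 0:2) {
        bias[a * per + 5L] <- log(8 / (cfg$input_size / cfg$strides[s])^2)
        bias[a * per + 5L + seq_len(cfg$n_classes)] <-
          log(0.6 / (cfg$n_classes - 0.99))
      }
      hu <- init_cbs(cw[2 + s], no, 1, act = FALSE, bn = FALSE,
                     bias_init = bias)
      hu$par$w <- hu$par$w * 0.1   # keep initial boxes on the anchor prior
      add("unit", c(p3, p4, p5)[s], hu,
          tag = paste0("head", s), head_scale = s)
    }
    structure(list(cfg = cfg, nodes = nodes, channels = cw),
              class = "tflos_model")
  })
}

#' @export
print.tflos_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Single-stage tea-flower detector\n")
  cat(sprintf("  input %dpx, %d classes, width x%.3g, depth x%.3g\n",
              cfg$input_size, cfg$n_classes, cfg$width_multiple,
              cfg$depth_multiple))
  cat(sprintf("  blocks: SE=%s, ARConv stages=[%s], CAAFT=%s\n",
              cfg$use_se, paste(cfg$arconv_stages, collapse = ","),
              cfg$use_caaft))
  cat(sprintf("  %d graph nodes, %d parameters\n", length(x$nodes),
              sum(vapply(x$nodes, function(n)
                if (is.null(n$unit)) 0L else par_count(n$unit), 0L))))
  invisible(x)
}

#' Forward pass through the detector
#'
#' @param model a `tflos_model`
#' @param x input tensor (N, 3, H, W)
#' @param training use batch statistics and keep caches for backward
#' @return list with `heads` (three raw head tensors, strides 8/16/32),
#'   `model` (updated running statistics when training) and, when training,
#'   `caches` and `outs`
#' @export
model_forward <- function(model, x, training = FALSE) {
  nodes <- model$nodes
  outs <- vector("list", length(nodes))
  caches <- if (training) vector("list", length(nodes)) else NULL
  get_in <- function(i) if (i == 0) x else outs[[i]]
  heads <- vector("list", 3)
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$op == "unit") {
      r <- unit_fwd(nd$unit, get_in(nd$from), training)
      outs[[i]] <- r$y
      if (training) {
        caches[[i]] <- r$cache
        nodes[[i]]$unit <- r$unit
      }
    } else if (nd$op == "upsample") {
      outs[[i]] <- cpp_upsample2_fw(get_in(nd$from))
    } else if (nd$op == "concat") {
      outs[[i]] <- tensor_cat(lapply(nd$from, get_in))
    }
    if (!is.null(nd$head_scale)) heads[[nd$head_scale]] <- outs[[i]]
  }
  model$nodes <- nodes
  list(heads = heads, model = model, caches = caches, outs = outs)
}

# Backward pass: ghead is a list of three gradients w.r.t. the head tensors.
# Returns gradient trees per node (NULL for parameter-free nodes).
model_backward <- function(model, x, fw, ghead) {
  nodes <- model$nodes
  n <- length(nodes)
  gouts <- vector("list", n)
  for (i in seq_len(n))
    if (!is.null(nodes[[i]]$head_scale))
      gouts[[i]] <- ghead[[nodes[[i]]$head_scale]]
  gpars <- vector("list", n)
  addg <- function(i, g) {
    if (i == 0) return(invisible())
    gouts[[i]] <<- if (is.null(gouts[[i]])) g else gouts[[i]] + g
  }
  for (i in rev(seq_len(n))) {
    g <- gouts[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    if (nd$op == "unit") {
      b <- unit_bwd(nd$unit, fw$caches[[i]], g)
      gpars[[i]] <- b$gpar
      addg(nd$from, b$gx)
    } else if (nd$op == "upsample") {
      addg(nd$from, cpp_upsample2_bw(g))
    } else if (nd$op == "concat") {
      cs <- vapply(nd$from, function(j)
        dim(if (j == 0) x else fw$outs[[j]])[2], 0)
      gs <- tensor_split(g, cs)
      for (k in seq_along(nd$from)) addg(nd$from[k], gs[[k]])
    }
    gouts[[i]] <- NULL  # free
  }
  gpars
}
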