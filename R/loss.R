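# Training loss: weighted sum of box (CIoU), objectness (BCE) and
# classification (BCE) terms, with anchor-ratio target assignment and
# cross-grid cell expansion.

#' Weighted total loss
#'
#' `loss = w_box * l_box + w_obj * l_obj + w_cls * l_cls`. The defaults are
#' the baseline-lineage weights (0.05, 1.0, 0.5).
#'
#' @param l_box,l_obj,l_cls non-negative loss terms
#' @param w_box,w_obj,w_cls non-negative weights
#' @return the weighted sum
#' @export
total_loss <- function(l_box, l_obj, l_cls,
                       w_box = 0.05, w_obj = 1.0, w_cls = 0.5) {
  if (any(c(w_box, w_obj, w_cls) < 0)) stop("weights must be non-negative")
  w_box * l_box + w_obj * l_obj + w_cls * l_cls
}

#' Confidence score of a detection
#'
#' The product `Pr(object) * IoU(pred, truth) * Pr(class)`.
#'
#' @param pr_object objectness probability in `[0, 1]`
#' @param iou box IoU in `[0, 1]`
#' @param pr_class class probability in `[0, 1]`
#' @return confidence in `[0, 1]`
#' @export
confidence_score <- function(pr_object, iou, pr_class) {
  v <- c(pr_object, iou, pr_class)
  if (any(v < 0 | v > 1)) stop("all factors must lie in [0, 1]")
  pr_object * iou * pr_class
}

# complete IoU between boxes in (cx, cy, w, h) form; rows paired
ciou_rows <- function(p, t, eps = 1e-9) {
  px1 <- p[, 1] - p[, 3] / 2; px2 <- p[, 1] + p[, 3] / 2
  py1 <- p[, 2] - p[, 4] / 2; py2 <- p[, 2] + p[, 4] / 2
  tx1 <- t[, 1] - t[, 3] / 2; tx2 <- t[, 1] + t[, 3] / 2
  ty1 <- t[, 2] - t[, 4] / 2; ty2 <- t[, 2] + t[, 4] / 2
  iw <- pmax(pmin(px2, tx2) - pmax(px1, tx1), 0)
  ih <- pmax(pmin(py2, ty2) - pmax(py1, ty1), 0)
  inter <- iw * ih
  union <- p[, 3] * p[, 4] + t[, 3] * t[, 4] - inter + eps
  iou <- inter / union
  cw <- pmax(px2, tx2) - pmin(px1, tx1)
  ch <- pmax(py2, ty2) - pmin(py1, ty1)
  c2 <- cw^2 + ch^2 + eps
  rho2 <- (p[, 1] - t[, 1])^2 + (p[, 2] - t[, 2])^2
  v <- (4 / pi^2) * (atan(t[, 3] / (t[, 4] + eps)) -
                     atan(p[, 3] / (p[, 4] + eps)))^2
  alpha <- v / (1 - iou + v + eps)       # treated as constant in the gradient
  iou - rho2 / c2 - alpha * v
}

# gradient of ciou w.r.t. the predicted (cx, cy, w, h), central differences
ciou_grad <- function(p, t, h = 1e-4) {
  g <- matrix(0, nrow(p), 4)
  for (k in 1:4) {
    pp <- p; pp[, k] <- pp[, k] + h
    pm <- p; pm[, k] <- pm[, k] - h
    g[, k] <- (ciou_rows(pp, t) - ciou_rows(pm, t)) / (2 * h)
  }
  g
}

# Assign labels to (scale, anchor, cell) triplets.
# labels: matrix (img, class, cx, cy, w, h) normalized; img 1-based.
# Returns per scale a data.frame with image b, anchor a, cell gj/gi
# (0-based), target box in grid units and class.
build_targets <- function(labels, cfg, anchor_t = 4) {
  lapply(1:3, function(s) {
    empty <- data.frame(b = integer(0), a = integer(0), gj = integer(0),
                        gi = integer(0), tx = numeric(0), ty = numeric(0),
                        tw = numeric(0), th = numeric(0), cls = integer(0))
    if (NROW(labels) == 0) return(empty)
    grid <- cfg$input_size / cfg$strides[s]
    gxy <- labels[, 3:4, drop = FALSE] * grid
    gwh <- labels[, 5:6, drop = FALSE] * grid
    anc <- cfg$anchors[s, , ] / cfg$strides[s]   # 3 x 2, grid units
    rows <- NULL
    for (a in 1:3) {
      r <- cbind(gwh[, 1] / anc[a, 1], gwh[, 2] / anc[a, 2])
      keep <- pmax(r[, 1], 1 / r[, 1], r[, 2], 1 / r[, 2]) < anchor_t
      if (!any(keep)) next
      idx <- which(keep)
      for (i in idx) {
        cx <- gxy[i, 1]; cy <- gxy[i, 2]
        ci <- floor(cx); cj <- floor(cy)
        cells <- list(c(ci, cj))
        fx <- cx - ci; fy <- cy - cj
        if (fx < 0.5 && ci > 0) cells <- c(cells, list(c(ci - 1, cj)))
        if (fx >= 0.5 && ci < grid - 1) cells <- c(cells, list(c(ci + 1, cj)))
        if (fy < 0.5 && cj > 0) cells <- c(cells, list(c(ci, cj - 1)))
        if (fy >= 0.5 && cj < grid - 1) cells <- c(cells, list(c(ci, cj + 1)))
        for (cc in cells)
          rows <- rbind(rows, c(labels[i, 1], a, cc[2], cc[1], cx, cy,
                                gwh[i, 1], gwh[i, 2], labels[i, 2]))
      }
    }
    if (is.null(rows)) return(empty)
    rows <- as.data.frame(rows)
    names(rows) <- c("b", "a", "gj", "gi", "tx", "ty", "tw", "th", "cls")
    # clamp cells to the grid (cross-grid expansion can leave the map)
    rows$gi <- pmin(pmax(rows$gi, 0), grid - 1)
    rows$gj <- pmin(pmax(rows$gj, 0), grid - 1)
    rows
  })
}

# Loss value and gradients w.r.t. the three raw head tensors.
# heads: list of (N, 3*(5+nc), Hg, Wg); labels as in build_targets.
# class_weights: optional per-class multipliers on the classification BCE
# (mitigates class imbalance, e.g. inverse label frequencies); NULL = off.
detector_loss <- function(heads, labels, cfg,
                          w_box = 0.05, w_obj = 1.0, w_cls = 0.5,
                          balance = c(4.0, 1.0, 0.4),
                          class_weights = NULL) {
  nc <- cfg$n_classes
  per <- 5L + nc
  N <- dim(heads[[1]])[1]
  targets <- build_targets(labels, cfg)
  l_box <- 0; l_cls <- 0; l_obj <- 0
  n_box <- 0; n_cls_el <- 0
  ghead <- lapply(heads, zeros_like)
  for (s in 1:3) {
    t5 <- heads[[s]]
    d <- dim(t5)
    Hg <- d[3]; Wg <- d[4]
    tobj_target <- array(0, c(N, 3, Hg, Wg))
    tg <- targets[[s]]
    gsc <- ghead[[s]]
    if (nrow(tg) > 0) {
      anc <- matrix(cfg$anchors[s, , ] / cfg$strides[s], 3, 2)
      ch0 <- (tg$a - 1) * per
      idx <- function(k) cbind(tg$b, ch0 + k, tg$gj + 1, tg$gi + 1)
      tx <- t5[idx(1)]; ty <- t5[idx(2)]
      tw <- t5[idx(3)]; th <- t5[idx(4)]
      sx <- sigmoid(tx); sy <- sigmoid(ty)
      sw <- sigmoid(tw); sh <- sigmoid(th)
      pcx <- 2 * sx - 0.5 + tg$gi
      pcy <- 2 * sy - 0.5 + tg$gj
      pw <- (2 * sw)^2 * anc[tg$a, 1]
      ph <- (2 * sh)^2 * anc[tg$a, 2]
      P <- cbind(pcx, pcy, pw, ph)
      Tt <- cbind(tg$tx, tg$ty, tg$tw, tg$th)
      ci <- ciou_rows(P, Tt)
      nT <- nrow(tg)
      l_box <- l_box + sum(1 - ci)
      n_box <- n_box + nT
      gci <- ciou_grad(P, Tt)            # d ciou / d (pcx,pcy,pw,ph)
      # d l_box/d raw = -(1/nTtot later) * gci * chain
      gtx <- -gci[, 1] * 2 * sx * (1 - sx)
      gty <- -gci[, 2] * 2 * sy * (1 - sy)
      gtw <- -gci[, 3] * 2 * pw * (1 - sw)
      gth <- -gci[, 4] * 2 * ph * (1 - sh)
      gsc[idx(1)] <- gsc[idx(1)] + gtx
      gsc[idx(2)] <- gsc[idx(2)] + gty
      gsc[idx(3)] <- gsc[idx(3)] + gtw
      gsc[idx(4)] <- gsc[idx(4)] + gth
      # objectness target: detached clamped ciou (duplicate cells: max)
      oi <- cbind(tg$b, tg$a, tg$gj + 1, tg$gi + 1)
      vals <- pmax(ci, 0)
      ord <- order(vals)                  # later (larger) wins
      tobj_target[oi[ord, , drop = FALSE]] <- vals[ord]
      # classification BCE over assigned cells
      if (nc > 1) {
        for (k in seq_len(nc)) {
          tk <- t5[idx(5 + k)]
          pk <- sigmoid(tk)
          yk <- as.numeric(tg$cls == (k - 1))
          wk <- if (is.null(class_weights)) 1 else class_weights[k]
          l_cls <- l_cls + wk * sum(-yk * log(pmax(pk, 1e-12)) -
                                      (1 - yk) * log(pmax(1 - pk, 1e-12)))
          gsc[idx(5 + k)] <- gsc[idx(5 + k)] + wk * (pk - yk)
        }
        n_cls_el <- n_cls_el + nT * nc
      }
    }
    # objectness BCE over the full grid
    och <- 5L + (0:2) * per              # objectness channels per anchor
    tob <- t5[, och, , , drop = FALSE]
    pob <- sigmoid(tob)
    yob <- tobj_target
    l_obj <- l_obj + balance[s] *
      mean(-yob * log(pmax(pob, 1e-12)) -
             (1 - yob) * log(pmax(1 - pob, 1e-12)))
    gsc[, och, , ] <- gsc[, och, , , drop = FALSE] +
      w_obj * balance[s] * (array(pob, dim(pob)) - yob) / length(pob)
    ghead[[s]] <- gsc
  }
  if (n_box > 0) l_box <- l_box / n_box
  # box and cls gradients were accumulated as unnormalized sums; apply the
  # weights and normalizers now (objectness was scaled on accumulation)
  for (s in 1:3) {
    d <- dim(ghead[[s]])
    per_s <- per
    och <- 5L + (0:2) * per_s
    boxcls <- setdiff(seq_len(d[2]), och)
    if (n_box > 0 || n_cls_el > 0) {
      scale_box <- if (n_box > 0) w_box / n_box else 0
      scale_cls <- if (n_cls_el > 0) w_cls / n_cls_el else 0
      bch <- as.vector(outer(1:4, (0:2) * per_s, "+"))
      cch <- setdiff(boxcls, bch)
      ghead[[s]][, bch, , ] <- ghead[[s]][, bch, , ] * scale_box
      if (length(cch)) ghead[[s]][, cch, , ] <- ghead[[s]][, cch, , ] *
          scale_cls
    }
  }
  if (n_cls_el > 0) l_cls <- l_cls / n_cls_el
  list(loss = total_loss(l_box, l_obj, l_cls, w_box, w_obj, w_cls),
       l_box = l_box, l_obj = l_obj, l_cls = l_cls,
       ghead = ghead, n_assigned = n_box)
}
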