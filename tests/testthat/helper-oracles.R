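# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use plain loops.

oracle_ca_pool <- function(x) {
  d <- dim(x)
  z_h <- array(0, c(d[1], d[2], d[3], 1))
  z_w <- array(0, c(d[1], d[2], 1, d[4]))
  for (n in seq_len(d[1])) for (c in seq_len(d[2])) {
    for (h in seq_len(d[3])) {
      s <- 0
      for (w in seq_len(d[4])) s <- s + x[n, c, h, w]
      z_h[n, c, h, 1] <- s / d[4]
    }
    for (w in seq_len(d[4])) {
      s <- 0
      for (h in seq_len(d[3])) s <- s + x[n, c, h, w]
      z_w[n, c, 1, w] <- s / d[3]
    }
  }
  list(z_h = z_h, z_w = z_w)
}

oracle_reweight <- function(x, a_h, a_w) {
  d <- dim(x)
  y <- array(0, d)
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    for (h in seq_len(d[3])) for (w in seq_len(d[4]))
      y[n, c, h, w] <- x[n, c, h, w] * a_h[n, c, h] * a_w[n, c, w]
  y
}

oracle_aft <- function(x, p) {
  T <- nrow(x); d <- ncol(x)
  Q <- matrix(0, T, d); K <- Q; V <- Q
  for (t in seq_len(T)) for (j in seq_len(d)) {
    for (i in seq_len(d)) {
      Q[t, j] <- Q[t, j] + x[t, i] * p$wq[i, j]
      K[t, j] <- K[t, j] + x[t, i] * p$wk[i, j]
      V[t, j] <- V[t, j] + x[t, i] * p$wv[i, j]
    }
    Q[t, j] <- Q[t, j] + p$bq[j]
    K[t, j] <- K[t, j] + p$bk[j]
    V[t, j] <- V[t, j] + p$bv[j]
  }
  Y <- matrix(0, T, d)
  for (j in seq_len(d)) {
    m <- max(K[, j])
    e <- exp(K[, j] - m)
    u <- e / sum(e)
    ctx <- 0
    for (t in seq_len(T)) ctx <- ctx + u[t] * V[t, j]
    for (t in seq_len(T)) Y[t, j] <- (1 / (1 + exp(-Q[t, j]))) * ctx
  }
  Y
}

oracle_bilinear <- function(x, positions) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], nrow(positions)))
  for (m in seq_len(nrow(positions))) {
    yy <- positions[m, 1]; xx <- positions[m, 2]
    y0 <- floor(yy); x0 <- floor(xx)
    fy <- yy - y0; fx <- xx - x0
    for (n in seq_len(d[1])) for (c in seq_len(d[2])) {
      acc <- 0
      for (dy in 0:1) for (dx in 0:1) {
        ys <- y0 + dy + 1; xs <- x0 + dx + 1
        if (ys >= 1 && ys <= d[3] && xs >= 1 && xs <= d[4]) {
          wy <- if (dy == 1) fy else 1 - fy
          wx <- if (dx == 1) fx else 1 - fx
          acc <- acc + wy * wx * x[n, c, ys, xs]
        }
      }
      out[n, c, m] <- acc
    }
  }
  out
}

oracle_offsets <- function(h0, w0, k_h, k_w) {
  out <- matrix(0, k_h * k_w, 2)
  r <- 0
  for (a in seq_len(k_h)) for (b in seq_len(k_w)) {
    r <- r + 1
    out[r, 1] <- (a - (k_h + 1) / 2) * h0 / k_h
    out[r, 2] <- (b - (k_w + 1) / 2) * w0 / k_w
  }
  out
}

# exact all-point AP by explicit segment enumeration (independent of the
# cummax-envelope implementation)
oracle_ap <- function(conf, is_tp, n_truth) {
  ord <- order(-conf)
  tp <- cumsum(is_tp[ord]); fp <- cumsum(!is_tp[ord])
  prec <- tp / (tp + fp)
  rec <- tp / n_truth
  pts <- unique(c(0, rec))
  ap <- 0
  for (i in seq_along(pts)) {
    if (i == 1) next
    r0 <- pts[i - 1]; r1 <- pts[i]
    pmax_seg <- 0
    for (j in seq_along(rec))
      if (rec[j] >= r1 && prec[j] > pmax_seg) pmax_seg <- prec[j]
    ap <- ap + (r1 - r0) * pmax_seg
  }
  ap
}

# direct dense convolution oracle (stride 1, zero padding)
oracle_conv <- function(x, w, b, stride = 1, pad = 1) {
  d <- dim(x); dw <- dim(w)
  OH <- (d[3] + 2 * pad - dw[3]) %/% stride + 1
  OW <- (d[4] + 2 * pad - dw[4]) %/% stride + 1
  y <- array(0, c(d[1], dw[1], OH, OW))
  for (n in seq_len(d[1])) for (o in seq_len(dw[1]))
    for (oh in seq_len(OH)) for (ow in seq_len(OW)) {
      acc <- b[o]
      for (c in seq_len(d[2])) for (a in seq_len(dw[3]))
        for (bb in seq_len(dw[4])) {
          h <- (oh - 1) * stride + a - pad
          ww <- (ow - 1) * stride + bb - pad
          if (h >= 1 && h <= d[3] && ww >= 1 && ww <= d[4])
            acc <- acc + x[n, c, h, ww] * w[o, c, a, bb]
        }
      y[n, o, oh, ow] <- acc
    }
  y
}

# small helper: random scene dataset in a temp dir
make_tiny_dataset <- function(n = 12, image_size = 96, seed = 1,
                              split = c(0.6, 0.2, 0.2)) {
  dir <- tempfile("tinyds")
  sp <- easy_scene_spec(image_size = image_size, seed = seed)
  generate_dataset(sp, n, dir, split = split)
  dir
}
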