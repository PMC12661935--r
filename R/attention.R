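#' Attention blocks: squeeze-and-excitation, coordinate attention, and the
#' attention-free transformer
#'
#' These are the channel/spatial attention mechanisms used inside the
#' detector. Each has a functional forward (the documented contract) and a
#' trainable unit wrapper with a hand-written backward pass.
#'
#' @name attention
NULL

#' Squeeze-and-excitation parameters
#'
#' Two fully-connected transforms with a sigmoid gate. The reduced width is
#' `max(1, C / reduction_ratio)`.
#'
#' @param channels number of input channels C
#' @param reduction_ratio channel reduction ratio (default 16, the convention
#'   of the original mechanism)
#' @return an `se_params` list with weight matrices `w1` (Cr x C), `b1`,
#'   `w2` (C x Cr), `b2`
#' @export
se_params <- function(channels, reduction_ratio = 16) {
  stopifnot(channels >= 1, reduction_ratio >= 1)
  cr <- max(1L, channels %/% as.integer(reduction_ratio))
  list(w1 = matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr, channels),
       b1 = rep(0, cr),
       w2 = matrix(rnorm(channels * cr, sd = sqrt(1 / cr)), channels, cr),
       b2 = rep(0, channels),
       reduction_ratio = reduction_ratio)
}

#' Squeeze-and-excitation forward pass
#'
#' Global average pooling per channel (squeeze), two fully-connected layers
#' with ReLU and sigmoid (excitation), then per-channel rescaling of the
#' input by the resulting gate in (0,1). Output shape equals input shape.
#'
#' @param x feature map, 4-d array (N, C, H, W)
#' @param p parameters from [se_params()]
#' @return a feature map of the same shape; the gate matrix (N x C) is
#'   attached as attribute `"gate"`
#' @export
se_forward <- function(x, p) {
  check_fmap(x)
  d <- dim(x)
  if (nrow(p$w1) < 1 || ncol(p$w1) != d[2])
    stop("SE parameter width does not match channel count")
  z <- apply(x, c(1, 2), mean)          # (N, C) squeeze
  z <- matrix(z, d[1], d[2])
  u1 <- pmax(z %*% t(p$w1) + matrix(p$b1, d[1], length(p$b1), byrow = TRUE), 0)
  g <- sigmoid(u1 %*% t(p$w2) + matrix(p$b2, d[1], d[2], byrow = TRUE))
  y <- x * array(g, dim = d)            # (N,C) broadcasts over H, W
  attr(y, "gate") <- g
  y
}

init_se <- function(channels, reduction_ratio = 16) {
  p <- se_params(channels, reduction_ratio)
  list(cfg = list(type = "se", c = channels),
       par = list(w1 = p$w1, b1 = p$b1, w2 = p$w2, b2 = p$b2))
}

se_unit_fwd <- function(u, x, training = TRUE) {
  d <- dim(x)
  z <- matrix(apply(x, c(1, 2), mean), d[1], d[2])
  u1p <- z %*% t(u$par$w1) + matrix(u$par$b1, d[1], length(u$par$b1),
                                    byrow = TRUE)
  u1 <- pmax(u1p, 0)
  g <- sigmoid(u1 %*% t(u$par$w2) + matrix(u$par$b2, d[1], d[2], byrow = TRUE))
  y <- x * array(g, dim = d)
  list(y = y, cache = list(x = x, z = z, u1p = u1p, u1 = u1, g = g), unit = u)
}

se_unit_bwd <- function(u, cache, gy) {
  x <- cache$x; d <- dim(x)
  g <- cache$g
  gx <- gy * array(g, dim = d)
  gg <- matrix(apply(gy * x, c(1, 2), sum), d[1], d[2])
  gu2 <- gg * g * (1 - g)
  gw2 <- t(gu2) %*% cache$u1
  gb2 <- colSums(gu2)
  gu1 <- (gu2 %*% u$par$w2) * (cache$u1p > 0)
  gw1 <- t(gu1) %*% cache$z
  gb1 <- colSums(gu1)
  gz <- gu1 %*% u$par$w1
  gx <- gx + array(gz, dim = d) / (d[3] * d[4])
  list(gx = gx,
       gpar = list(par = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2)))
}

#' Coordinate-attention 1D pooling
#'
#' Factorizes global pooling into two directions: `z_h` averages each row
#' over the width axis (factor 1/W) and `z_w` averages each column over the
#' height axis (factor 1/H), giving direction-aware per-channel descriptors.
#'
#' @param x feature map, 4-d array (N, C, H, W)
#' @return list with `z_h` (N, C, H, 1) and `z_w` (N, C, 1, W)
#' @export
ca_pool <- function(x) {
  check_fmap(x)
  d <- dim(x)
  z_h <- array(apply(x, c(1, 2, 3), mean), c(d[1], d[2], d[3], 1))
  z_w <- aperm(array(apply(x, c(1, 2, 4), mean), c(d[1], d[2], d[4], 1)),
               c(1, 2, 4, 3))
  list(z_h = z_h, z_w = z_w)
}

#' Coordinate-attention parameters
#'
#' The concatenated descriptors are encoded by a shared 1x1 transform
#' (channel reduction, ReLU), split back into the two directions, and each
#' direction is projected to C channels and sigmoid-activated.
#'
#' @param channels number of channels C
#' @param reduction channel reduction of the shared encoder (default 8)
#' @return a `ca_params` list
#' @export
ca_params <- function(channels, reduction = 8) {
  mid <- max(2L, channels %/% as.integer(reduction))
  list(w1 = matrix(rnorm(mid * channels, sd = sqrt(2 / channels)),
                   mid, channels),
       b1 = rep(0, mid),
       wh = matrix(rnorm(channels * mid, sd = sqrt(1 / mid)), channels, mid),
       bh = rep(0, channels),
       ww = matrix(rnorm(channels * mid, sd = sqrt(1 / mid)), channels, mid),
       bw = rep(0, channels))
}

# Encode pooled descriptors into the two sigmoid attention profiles.
ca_attention <- function(d, p) {
  zh <- d$z_h; zw <- d$z_w
  dn <- dim(zh)
  N <- dn[1]; C <- dn[2]; H <- dn[3]; W <- dim(zw)[4]
  # columns are (n, position); shared encoder acts on channels
  Zh <- matrix(aperm(array(zh, c(N, C, H)), c(2, 1, 3)), C, N * H)
  Zw <- matrix(aperm(array(zw, c(N, C, W)), c(2, 1, 3)), C, N * W)
  Z <- cbind(Zh, Zw)
  M <- pmax(p$w1 %*% Z + p$b1, 0)
  Mh <- M[, seq_len(N * H), drop = FALSE]
  Mw <- M[, N * H + seq_len(N * W), drop = FALSE]
  ah <- sigmoid(p$wh %*% Mh + p$bh)      # C x (N*H)
  aw <- sigmoid(p$ww %*% Mw + p$bw)      # C x (N*W)
  list(a_h = aperm(array(ah, c(C, N, H)), c(2, 1, 3)),
       a_w = aperm(array(aw, c(C, N, W)), c(2, 1, 3)))
}

#' Coordinate-attention reweighting
#'
#' Re-weights the input by the two direction attentions:
#' `y[n,c,h,w] = x[n,c,h,w] * a_h[n,c,h] * a_w[n,c,w]`, where the attentions
#' are sigmoid activations of the encoded descriptors.
#'
#' @param x feature map (N, C, H, W)
#' @param d descriptors from [ca_pool()] (must match the shape of `x`)
#' @param p parameters from [ca_params()]
#' @return feature map of the same shape, attentions attached as attributes
#'   `"a_h"` (N, C, H) and `"a_w"` (N, C, W)
#' @export
ca_reweight <- function(x, d, p) {
  check_fmap(x)
  dn <- dim(x)
  if (!all(dim(d$z_h)[1:3] == dn[1:3]) || dim(d$z_w)[4] != dn[4])
    stop("descriptor shapes do not match the input feature map")
  a <- ca_attention(d, p)
  # broadcast a_h over w and a_w over h
  Aw <- aperm(array(a$a_w, c(dn[1], dn[2], dn[4], dn[3])), c(1, 2, 4, 3))
  Ah <- array(a$a_h, dim = dn)
  y <- x * Ah * Aw
  attr(y, "a_h") <- a$a_h
  attr(y, "a_w") <- a$a_w
  y
}

#' Attention-free-transformer parameters
#'
#' Linear maps on the model dimension `d` for queries, keys and values, with
#' the element-wise non-linearities of the gated formulation: a sigmoid
#' output gate on Q' and a softmax over the sequence dimension on K'
#' (acting as a forget gate), pooled by summation.
#'
#' @param d model dimension
#' @param sigma_q,sigma_k element-wise non-linearities: `"sigmoid"` /
#'   `"softmax"` (over the sequence dimension) / `"identity"`
#' @param pool reduction over the sequence dimension, `"sum"` or `"mean"`
#' @return an `aft_params` list with `wq`, `wk`, `wv` (d x d) and biases
#' @export
aft_params <- function(d, sigma_q = "sigmoid", sigma_k = "softmax",
                       pool = "sum") {
  list(wq = matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d), bq = rep(0, d),
       wk = matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d), bk = rep(0, d),
       wv = matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d), bv = rep(0, d),
       sigma_q = sigma_q, sigma_k = sigma_k, pool = pool)
}

softmax_cols <- function(m) {
  # softmax over rows (sequence dim) for each column independently
  m <- sweep(m, 2, apply(m, 2, max), "-")
  e <- exp(m)
  sweep(e, 2, colSums(e), "/")
}

#' Attention-free-transformer forward pass
#'
#' Computes `Y = sigma_q(Q') * Pool(sigma_k(K') * V')` where Q', K', V' are
#' linear transforms of the input sequence, `sigma_q` is a sigmoid output
#' gate, `sigma_k` a softmax over the sequence dimension, and `Pool` sums
#' over the sequence. No T x T attention matrix is materialized; the extra
#' memory is O(T * d).
#'
#' @param x_seq sequence, a T x d matrix
#' @param p parameters from [aft_params()]
#' @return a T x d matrix
#' @export
aft_forward <- function(x_seq, p) {
  x_seq <- as.matrix(x_seq)
  if (ncol(x_seq) != nrow(p$wq)) stop("model dimension mismatch")
  sq <- if (is.null(p$sigma_q)) "sigmoid" else p$sigma_q
  sk <- if (is.null(p$sigma_k)) "softmax" else p$sigma_k
  pool <- if (is.null(p$pool)) "sum" else p$pool
  Q <- x_seq %*% p$wq + matrix(p$bq, nrow(x_seq), ncol(x_seq), byrow = TRUE)
  K <- x_seq %*% p$wk + matrix(p$bk, nrow(x_seq), ncol(x_seq), byrow = TRUE)
  V <- x_seq %*% p$wv + matrix(p$bv, nrow(x_seq), ncol(x_seq), byrow = TRUE)
  G <- switch(sq, sigmoid = sigmoid(Q), identity = Q,
              stop("unknown sigma_q"))
  U <- switch(sk, softmax = softmax_cols(K), sigmoid = sigmoid(K),
              identity = K, stop("unknown sigma_k"))
  ctx <- switch(pool, sum = colSums(U * V), mean = colMeans(U * V),
                stop("unknown pool"))
  G * matrix(ctx, nrow(x_seq), ncol(x_seq), byrow = TRUE)
}

#' Combined coordinate-attention + attention-free-transformer block
#'
#' Applies coordinate attention (pooling + reweighting) to the feature map,
#' flattens the spatial positions to a sequence of length H*W (height
#' fastest), applies the attention-free transformer, restores the (C, H, W)
#' layout, and adds the result to the reweighted map through a residual
#' connection. Shape is preserved.
#'
#' @param x feature map (N, C, H, W)
#' @param params a unit from [init_caaft()] or its `$par` list
#' @param ca_first apply coordinate attention before the AFT (the default
#'   wiring); `FALSE` swaps the order for ablation
#' @return feature map of the same shape
#' @export
caaft_forward <- function(x, params, ca_first = TRUE) {
  if (!is.null(params$par)) params <- params$par
  check_fmap(x)
  d <- dim(x)
  aftp <- params[c("wq", "bq", "wk", "bk", "wv", "bv")]
  apply_aft <- function(z) {
    y <- z
    for (n in seq_len(d[1])) {
      seqm <- matrix(aperm(array(z[n, , , , drop = FALSE],
                                 d[2:4]), c(2, 3, 1)), d[3] * d[4], d[2])
      out <- aft_forward(seqm, aftp)
      y[n, , , ] <- y[n, , , ] + aperm(array(out, c(d[3], d[4], d[2])),
                                       c(3, 1, 2))
    }
    y
  }
  apply_ca <- function(z) {
    out <- ca_reweight(z, ca_pool(z), params)
    attributes(out) <- list(dim = d)
    out
  }
  if (ca_first) apply_aft(apply_ca(x)) else apply_ca(apply_aft(x))
}

#' @rdname caaft_forward
#' @param channels number of channels C (the AFT model dimension)
#' @param reduction coordinate-attention encoder reduction
#' @export
init_caaft <- function(channels, reduction = 8) {
  cp <- ca_params(channels, reduction)
  ap <- aft_params(channels)
  # trainable arrays only; the unit always uses the default gates
  list(cfg = list(type = "caaft", c = channels),
       par = c(cp, ap[c("wq", "bq", "wk", "bk", "wv", "bv")]))
}

caaft_unit_fwd <- function(u, x, training = TRUE) {
  p <- u$par
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  pool <- ca_pool(x)
  a <- ca_attention(pool, p)
  Ah <- array(a$a_h, dim = d)
  Aw <- aperm(array(a$a_w, c(N, C, W, H)), c(1, 2, 4, 3))
  xca <- x * Ah * Aw
  y <- xca
  aft_cache <- vector("list", N)
  for (n in seq_len(N)) {
    sq <- matrix(aperm(array(xca[n, , , , drop = FALSE], d[2:4]),
                       c(2, 3, 1)), H * W, C)
    Q <- sq %*% p$wq + matrix(p$bq, H * W, C, byrow = TRUE)
    K <- sq %*% p$wk + matrix(p$bk, H * W, C, byrow = TRUE)
    V <- sq %*% p$wv + matrix(p$bv, H * W, C, byrow = TRUE)
    G <- sigmoid(Q)
    U <- softmax_cols(K)
    ctx <- colSums(U * V)
    out <- G * matrix(ctx, H * W, C, byrow = TRUE)
    y[n, , , ] <- y[n, , , ] + aperm(array(out, c(H, W, C)), c(3, 1, 2))
    aft_cache[[n]] <- list(sq = sq, G = G, U = U, V = V, ctx = ctx)
  }
  list(y = y,
       cache = list(x = x, pool = pool, a = a, Ah = Ah, Aw = Aw, xca = xca,
                    aft = aft_cache),
       unit = u)
}

caaft_unit_bwd <- function(u, cache, gy) {
  p <- u$par
  x <- cache$x
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  gxca <- gy  # residual path
  gwq <- 0 * p$wq; gbq <- 0 * p$bq
  gwk <- 0 * p$wk; gbk <- 0 * p$bk
  gwv <- 0 * p$wv; gbv <- 0 * p$bv
  for (n in seq_len(N)) {
    ac <- cache$aft[[n]]
    gout <- matrix(aperm(array(gy[n, , , , drop = FALSE], d[2:4]),
                         c(2, 3, 1)), H * W, C)
    G <- ac$G; U <- ac$U; V <- ac$V
    ctxm <- matrix(ac$ctx, H * W, C, byrow = TRUE)
    gG <- gout * ctxm
    gctx <- colSums(gout * G)
    gQ <- gG * G * (1 - G)
    gV <- U * matrix(gctx, H * W, C, byrow = TRUE)
    gU <- V * matrix(gctx, H * W, C, byrow = TRUE)
    # softmax backward over the sequence dimension per feature column
    gK <- U * sweep(gU, 2, colSums(U * gU), "-")
    gwq <- gwq + t(ac$sq) %*% gQ; gbq <- gbq + colSums(gQ)
    gwk <- gwk + t(ac$sq) %*% gK; gbk <- gbk + colSums(gK)
    gwv <- gwv + t(ac$sq) %*% gV; gbv <- gbv + colSums(gV)
    gsq <- gQ %*% t(p$wq) + gK %*% t(p$wk) + gV %*% t(p$wv)
    gxca[n, , , ] <- gxca[n, , , ] +
      aperm(array(gsq, c(H, W, C)), c(3, 1, 2))
  }
  # through the reweighting y_ca = x * Ah * Aw
  Ah <- cache$Ah; Aw <- cache$Aw
  gx <- gxca * Ah * Aw
  gAh3 <- apply(gxca * x * Aw, c(1, 2, 3), sum)          # (N, C, H)
  gAw3 <- apply(gxca * x * Ah, c(1, 2, 4), sum)          # (N, C, W)
  ah <- cache$a$a_h; aw <- cache$a$a_w
  gth <- gAh3 * ah * (1 - ah)
  gtw <- gAw3 * aw * (1 - aw)
  Gth <- matrix(aperm(gth, c(2, 1, 3)), C, N * H)
  Gtw <- matrix(aperm(gtw, c(2, 1, 3)), C, N * W)
  # recompute encoder intermediates (cheap relative to caching them)
  zh <- cache$pool$z_h; zw <- cache$pool$z_w
  Zh <- matrix(aperm(array(zh, c(N, C, H)), c(2, 1, 3)), C, N * H)
  Zw <- matrix(aperm(array(zw, c(N, C, W)), c(2, 1, 3)), C, N * W)
  Z <- cbind(Zh, Zw)
  Mpre <- p$w1 %*% Z + p$b1
  M <- pmax(Mpre, 0)
  Mh <- M[, seq_len(N * H), drop = FALSE]
  Mw <- M[, N * H + seq_len(N * W), drop = FALSE]
  gwh <- Gth %*% t(Mh); gbh <- rowSums(Gth)
  gww <- Gtw %*% t(Mw); gbw <- rowSums(Gtw)
  gM <- cbind(t(p$wh) %*% Gth, t(p$ww) %*% Gtw) * (Mpre > 0)
  gw1 <- gM %*% t(Z); gb1 <- rowSums(gM)
  gZ <- t(p$w1) %*% gM
  gZh <- aperm(array(gZ[, seq_len(N * H), drop = FALSE], c(C, N, H)),
               c(2, 1, 3))
  gZw <- aperm(array(gZ[, N * H + seq_len(N * W), drop = FALSE], c(C, N, W)),
               c(2, 1, 3))
  # pooling backward: z_h averaged over w (1/W), z_w averaged over h (1/H)
  gx <- gx + array(gZh, dim = d) / W +
    aperm(array(gZw, c(N, C, W, H)), c(1, 2, 4, 3)) / H
  list(gx = gx,
       gpar = list(par = list(w1 = gw1, b1 = gb1, wh = gwh, bh = gbh,
                              ww = gww, bw = gbw,
                              wq = gwq, bq = gbq, wk = gwk, bk = gbk,
                              wv = gwv, bv = gbv)))
}
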