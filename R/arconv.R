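#' Adaptive rectangular convolution
#'
#' A convolution whose kernel height and width are predicted from the input:
#' two small subnetworks output per-pixel height/width fields (sigmoid-scaled
#' into `(b, a + b)`), the spatial means of those fields set an odd kernel
#' size, a rectangular sampling grid scaled per pixel is gathered by bilinear
#' interpolation (zero padding outside the map), and the gathered sampling
#' map is convolved with a learned kernel bank and modulated by per-pixel
#' affine fields `M` and `B`: `y = SK (*) S .* M (+) B`.
#'
#' @name arconv
NULL

#' Odd kernel size from a mean field value
#'
#' Floors the mean predicted extent and decrements even values so the kernel
#' size is always odd and at least 1.
#'
#' @param mean_value positive real, the spatial mean of a predicted
#'   height/width field
#' @return an odd integer >= 1
#' @export
kernel_size <- function(mean_value) {
  if (!is.numeric(mean_value) || length(mean_value) != 1 ||
      !is.finite(mean_value) || mean_value <= 0)
    stop("mean_value must be a positive finite scalar")
  k <- floor(mean_value)
  if (k < 1) return(1L)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k - 1L
  max(1L, k)
}

#' Rectangular sampling offsets
#'
#' Builds the offset matrix `R = Z0 * G` where `G` spans the integer offsets
#' `-(k-1)/2 ... (k-1)/2` in each axis and `Z0 = (h0/k_h, w0/k_w)` rescales
#' the grid to the predicted extent. The centre offset is (0, 0) and the
#' matrix has `k_h * k_w` rows ordered row-major (dy outer, dx inner).
#'
#' @param h0,w0 predicted extents at the centre pixel (positive reals)
#' @param k_h,k_w odd kernel sizes
#' @return a `k_h * k_w` x 2 matrix of (dy, dx) offsets
#' @export
build_offsets <- function(h0, w0, k_h, k_w) {
  if (k_h %% 2L == 0L || k_w %% 2L == 0L)
    stop("kernel sizes must be odd")
  ga <- seq.int(-(k_h - 1L) / 2L, (k_h - 1L) / 2L)
  gb <- seq.int(-(k_w - 1L) / 2L, (k_w - 1L) / 2L)
  G <- cbind(rep(ga, each = k_w), rep(gb, times = k_h))
  cbind(G[, 1] * (h0 / k_h), G[, 2] * (w0 / k_w))
}

#' Bilinear sampling of a feature map
#'
#' Samples each channel of `x` at real-valued positions with bilinear
#' interpolation; positions outside the map contribute zero (zero padding).
#' Integer positions return the stored value exactly.
#'
#' @param x feature map (N, C, H, W)
#' @param positions an M x 2 matrix of (y, x) positions in 0-based pixel
#'   coordinates
#' @return an (N, C, M) array of sampled values
#' @export
bilinear_sample <- function(x, positions) {
  check_fmap(x)
  positions <- matrix(positions, ncol = 2)
  d <- dim(x)
  M <- nrow(positions)
  py <- array(rep(positions[, 1], each = d[1]), c(d[1], M, 1, 1))
  px <- array(rep(positions[, 2], each = d[1]), c(d[1], M, 1, 1))
  S <- cpp_bilinear_sample(x, py, px)
  array(S, c(d[1], d[2], M))
}

#' Predict per-pixel kernel height and width fields
#'
#' Each field is `a * sigmoid(f(x)) + b` where `f` is a small subnetwork
#' (3x3 conv, batch norm, SiLU, 1x1 conv to one channel), so every entry
#' lies in the open interval `(b, a + b)`.
#'
#' @param x feature map (N, C, H, W)
#' @param params an `arconv` unit from [init_arconv()]
#' @return list with `h_map`, `w_map` (N, 1, H, W), their means `h_bar`,
#'   `w_bar`, and the derived odd sizes `k_h`, `k_w`
#' @export
predict_hw <- function(x, params) {
  u <- params
  if (u$cfg$a1 <= 0 || u$cfg$a2 <= 0) stop("scale factors a must be positive")
  r <- arconv_hw_fwd(u, x, training = FALSE)
  list(h_map = r$h_map, w_map = r$w_map, h_bar = r$h_bar, w_bar = r$w_bar,
       k_h = r$k_h, k_w = r$k_w)
}

# kernel bank extent: largest odd size reachable given the scale bounds
arconv_kmax <- function(a, b) {
  k <- kernel_size(max(a + b, 1))
  max(1L, k)
}

#' @rdname arconv
#' @param c1,c2 input/output channels
#' @param a,b sigmoid scale/shift for both axes (field range `(b, a+b)`,
#'   default 6 and 1: kernel extents between 1 and 7 pixels)
#' @param subnet_width hidden width of the height/width subnetworks
#' @export
init_arconv <- function(c1, c2, a = 6, b = 1, subnet_width = 8) {
  if (a <= 0) stop("scale factor a must be positive")
  kmax <- arconv_kmax(a, b)
  sk <- array(rnorm(c2 * c1 * kmax * kmax, sd = sqrt(2 / (c1 * 9))),
              c(c2, c1, kmax, kmax))
  mk_sub <- function() list(
    conv = init_cbs(c1, subnet_width, k = 3),
    head = init_cbs(subnet_width, 1L, k = 1, act = FALSE, bn = FALSE))
  mk_affine <- function(bias) {
    u <- init_cbs(c1, c2, k = 1, act = FALSE, bn = FALSE)
    u$par$w[] <- 0
    u$par$b[] <- bias
    u
  }
  f1 <- mk_sub(); f2 <- mk_sub()
  list(cfg = list(type = "arconv", c1 = c1, c2 = c2, a1 = a, b1 = b,
                  a2 = a, b2 = b, kmax = kmax),
       par = list(sk = sk),
       sub = list(f1c = f1$conv, f1h = f1$head,
                  f2c = f2$conv, f2h = f2$head,
                  mnet = mk_affine(1), bnet = mk_affine(0)))
}

arconv_hw_fwd <- function(u, x, training = TRUE) {
  r1a <- unit_fwd(u$sub$f1c, x, training); u$sub$f1c <- r1a$unit
  r1b <- unit_fwd(u$sub$f1h, r1a$y, training); u$sub$f1h <- r1b$unit
  r2a <- unit_fwd(u$sub$f2c, x, training); u$sub$f2c <- r2a$unit
  r2b <- unit_fwd(u$sub$f2h, r2a$y, training); u$sub$f2h <- r2b$unit
  s1 <- sigmoid(r1b$y); s2 <- sigmoid(r2b$y)
  h_map <- u$cfg$a1 * s1 + u$cfg$b1
  w_map <- u$cfg$a2 * s2 + u$cfg$b2
  h_bar <- mean(h_map); w_bar <- mean(w_map)
  list(h_map = h_map, w_map = w_map, h_bar = h_bar, w_bar = w_bar,
       k_h = kernel_size(h_bar), k_w = kernel_size(w_bar),
       s1 = s1, s2 = s2,
       c1a = r1a$cache, c1b = r1b$cache, c2a = r2a$cache, c2b = r2b$cache,
       unit = u)
}

# central kh x kw window of the kernel bank
arconv_sk_window <- function(sk, kh, kw) {
  kmax <- dim(sk)[3]
  oy <- (kmax - kh) %/% 2L
  ox <- (kmax - kw) %/% 2L
  sk[, , oy + seq_len(kh), ox + seq_len(kw), drop = FALSE]
}

arconv_unit_fwd <- function(u, x, training = TRUE) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (C != u$cfg$c1) stop("channel mismatch between input and kernel bank")
  hw <- arconv_hw_fwd(u, x, training)
  u <- hw$unit
  kh <- hw$k_h; kw <- hw$k_w
  K <- kh * kw
  ga <- rep(seq.int(-(kh - 1L) / 2L, (kh - 1L) / 2L), each = kw)
  gb <- rep(seq.int(-(kw - 1L) / 2L, (kw - 1L) / 2L), times = kh)
  base_h <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  base_w <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  py <- array(0, c(N, K, H, W)); px <- array(0, c(N, K, H, W))
  hmap <- array(hw$h_map, c(N, H, W)); wmap <- array(hw$w_map, c(N, H, W))
  for (k in seq_len(K)) {
    py[, k, , ] <- sweep(hmap * (ga[k] / kh), c(2, 3), base_h, "+")
    px[, k, , ] <- sweep(wmap * (gb[k] / kw), c(2, 3), base_w, "+")
  }
  S <- cpp_bilinear_sample(x, py, px)     # (N, C, K, P), p column-major (h,w)
  sk_sub <- arconv_sk_window(u$par$sk, kh, kw)
  OC <- u$cfg$c2
  SKm <- matrix(aperm(sk_sub, c(1, 4, 3, 2)), OC, K * C)
  yconv <- array(0, c(N, OC, H, W))
  P <- H * W
  for (n in seq_len(N)) {
    Smat <- matrix(aperm(array(S[n, , , ], c(C, K, P)), c(2, 1, 3)), K * C, P)
    yconv[n, , , ] <- array(SKm %*% Smat, c(OC, H, W))
  }
  rm_ <- unit_fwd(u$sub$mnet, x, training); u$sub$mnet <- rm_$unit
  rb_ <- unit_fwd(u$sub$bnet, x, training); u$sub$bnet <- rb_$unit
  y <- yconv * rm_$y + rb_$y
  list(y = y,
       cache = list(x = x, hw = hw, S = S, SKm = SKm, kh = kh, kw = kw,
                    ga = ga, gb = gb, py = py, px = px, yconv = yconv,
                    M = rm_$y, cm = rm_$cache, cb = rb_$cache),
       unit = u)
}

arconv_unit_bwd <- function(u, cache, gy) {
  x <- cache$x
  d <- dim(x)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  OC <- u$cfg$c2
  kh <- cache$kh; kw <- cache$kw; K <- kh * kw; P <- H * W
  bb <- unit_bwd(u$sub$bnet, cache$cb, gy)
  bm <- unit_bwd(u$sub$mnet, cache$cm, gy * cache$yconv)
  gyconv <- gy * cache$M
  SKm <- cache$SKm
  gSKm <- matrix(0, OC, K * C)
  gS <- array(0, dim(cache$S))
  for (n in seq_len(N)) {
    Smat <- matrix(aperm(array(cache$S[n, , , ], c(C, K, P)), c(2, 1, 3)),
                   K * C, P)
    Gc <- matrix(gyconv[n, , , ], OC, P)
    gSKm <- gSKm + Gc %*% t(Smat)
    gSmat <- t(SKm) %*% Gc               # (K*C, P)
    gS[n, , , ] <- aperm(array(gSmat, c(K, C, P)), c(2, 1, 3))
  }
  bs <- cpp_bilinear_sample_bw(x, cache$py, cache$px, gS)
  gx <- bs$gx + bb$gx + bm$gx
  # position gradients back to the height/width fields
  ga <- cache$ga; gb <- cache$gb
  gh_map <- array(0, c(N, 1, H, W)); gw_map <- array(0, c(N, 1, H, W))
  for (k in seq_len(K)) {
    gh_map[, 1, , ] <- gh_map[, 1, , ] + bs$gpy[, k, , ] * (ga[k] / kh)
    gw_map[, 1, , ] <- gw_map[, 1, , ] + bs$gpx[, k, , ] * (gb[k] / kw)
  }
  hw <- cache$hw
  gs1 <- gh_map * u$cfg$a1 * hw$s1 * (1 - hw$s1)
  gs2 <- gw_map * u$cfg$a2 * hw$s2 * (1 - hw$s2)
  b1h <- unit_bwd(u$sub$f1h, hw$c1b, gs1)
  b1c <- unit_bwd(u$sub$f1c, hw$c1a, b1h$gx)
  b2h <- unit_bwd(u$sub$f2h, hw$c2b, gs2)
  b2c <- unit_bwd(u$sub$f2c, hw$c2a, b2h$gx)
  gx <- gx + b1c$gx + b2c$gx
  # scatter kernel gradient into the central window of the bank
  gsk <- array(0, dim(u$par$sk))
  kmax <- u$cfg$kmax
  oy <- (kmax - kh) %/% 2L; ox <- (kmax - kw) %/% 2L
  gsk[, , oy + seq_len(kh), ox + seq_len(kw)] <-
    aperm(array(gSKm, c(OC, kw, kh, C)), c(1, 4, 3, 2))
  list(gx = gx,
       gpar = list(par = list(sk = gsk),
                   sub = list(f1c = b1c$gpar, f1h = b1h$gpar,
                              f2c = b2c$gpar, f2h = b2h$gpar,
                              mnet = bm$gpar, bnet = bb$gpar)))
}

#' Adaptive rectangular convolution forward pass
#'
#' @param x feature map (N, C, H, W)
#' @param params an `arconv` unit from [init_arconv()]
#' @return feature map (N, C2, H, W); stride is 1 so the spatial size is
#'   preserved
#' @export
arconv_forward <- function(x, params) {
  check_fmap(x)
  arconv_unit_fwd(params, x, training = FALSE)$y
}
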