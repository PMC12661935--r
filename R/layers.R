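# Building blocks of the detector: Conv-BN-SiLU units, CSP bottlenecks (C3),
# SPPF, upsampling and concatenation, each with a hand-written backward pass.
# Units dispatch through unit_fwd()/unit_bwd() on cfg$type so composite blocks
# (C3, SPPF, attention, adaptive rectangular convolution) nest uniformly.

init_cbs <- function(c1, c2, k = 1, s = 1, p = NULL, act = TRUE, bn = TRUE,
                     bias_init = NULL) {
  if (is.null(p)) p <- k %/% 2L
  w <- array(rnorm(c2 * c1 * k * k, sd = sqrt(2 / (c1 * k * k))),
             c(c2, c1, k, k))
  par <- list(w = w)
  if (bn) {
    par$gamma <- rep(1, c2)
    par$beta <- rep(0, c2)
    st <- list(rm = rep(0, c2), rv = rep(1, c2))
  } else {
    par$b <- if (is.null(bias_init)) rep(0, c2) else bias_init
    st <- list()
  }
  list(cfg = list(type = "cbs", c1 = c1, c2 = c2, k = k, s = s, p = p,
                  act = act, bn = bn),
       par = par, st = st)
}

cbs_fwd <- function(u, x, training = TRUE) {
  cfg <- u$cfg
  b0 <- if (cfg$bn) rep(0, cfg$c2) else u$par$b
  z <- cpp_conv2d_fw(x, u$par$w, b0, as.integer(cfg$s), as.integer(cfg$p))
  cache <- list(x = x, z = z)
  if (cfg$bn) {
    r <- cpp_bn_fw(z, u$par$gamma, u$par$beta, u$st$rm, u$st$rv,
                   1e-5, training)
    if (training) {
      mom <- 0.03
      u$st$rm <- (1 - mom) * u$st$rm + mom * r$mean
      u$st$rv <- (1 - mom) * u$st$rv + mom * r$var
    }
    cache$bn_mean <- r$mean; cache$bn_var <- r$var; cache$a <- r$y
    y <- r$y
  } else y <- z
  if (cfg$act) {
    cache$pre <- y
    y <- cpp_leaky_fw(y, 0.1)
  }
  list(y = y, cache = cache, unit = u)
}

cbs_bwd <- function(u, cache, gy) {
  cfg <- u$cfg
  if (cfg$act) gy <- cpp_leaky_bw(cache$pre, gy, 0.1)
  gpar <- list()
  if (cfg$bn) {
    r <- cpp_bn_bw(cache$z, u$par$gamma, cache$bn_mean, cache$bn_var, 1e-5, gy)
    gy <- r$gx
    gpar$gamma <- r$ggamma
    gpar$beta <- r$gbeta
  }
  r <- cpp_conv2d_bw(cache$x, u$par$w, gy, as.integer(cfg$s),
                     as.integer(cfg$p))
  gpar$w <- r$gw
  if (!cfg$bn) gpar$b <- r$gb
  list(gx = r$gx, gpar = list(par = gpar))
}

# Bottleneck: cv1 1x1 -> cv2 3x3 (or ARConv), optional residual add.
init_bottleneck <- function(c1, c2, shortcut = TRUE, use_arconv = FALSE,
                            arconv_opts = list()) {
  ch <- c2
  cv2 <- if (use_arconv) {
    do.call(init_arconv, c(list(c1 = ch, c2 = c2), arconv_opts))
  } else init_cbs(ch, c2, k = 3)
  list(cfg = list(type = "bottleneck",
                  shortcut = shortcut && c1 == c2),
       sub = list(cv1 = init_cbs(c1, ch, k = 1), cv2 = cv2))
}

bottleneck_fwd <- function(u, x, training = TRUE) {
  r1 <- unit_fwd(u$sub$cv1, x, training); u$sub$cv1 <- r1$unit
  r2 <- unit_fwd(u$sub$cv2, r1$y, training); u$sub$cv2 <- r2$unit
  y <- if (u$cfg$shortcut) x + r2$y else r2$y
  list(y = y, cache = list(c1 = r1$cache, c2 = r2$cache), unit = u)
}

bottleneck_bwd <- function(u, cache, gy) {
  b2 <- unit_bwd(u$sub$cv2, cache$c2, gy)
  b1 <- unit_bwd(u$sub$cv1, cache$c1, b2$gx)
  gx <- b1$gx
  if (u$cfg$shortcut) gx <- gx + gy
  list(gx = gx, gpar = list(sub = list(cv1 = b1$gpar, cv2 = b2$gpar)))
}

# C3: CSP block with n bottlenecks on one branch, 1x1 bypass on the other.
init_c3 <- function(c1, c2, n = 1, shortcut = TRUE, use_arconv = FALSE,
                    arconv_opts = list()) {
  ch <- max(2L, c2 %/% 2L)
  sub <- list(cv1 = init_cbs(c1, ch, 1), cv2 = init_cbs(c1, ch, 1),
              cv3 = init_cbs(2L * ch, c2, 1))
  for (i in seq_len(n))
    sub[[paste0("m", i)]] <- init_bottleneck(ch, ch, shortcut, use_arconv,
                                             arconv_opts)
  list(cfg = list(type = "c3", n = n, ch = ch), sub = sub)
}

c3_fwd <- function(u, x, training = TRUE) {
  r1 <- unit_fwd(u$sub$cv1, x, training); u$sub$cv1 <- r1$unit
  r2 <- unit_fwd(u$sub$cv2, x, training); u$sub$cv2 <- r2$unit
  h <- r1$y
  mc <- vector("list", u$cfg$n)
  for (i in seq_len(u$cfg$n)) {
    nm <- paste0("m", i)
    rm <- unit_fwd(u$sub[[nm]], h, training)
    u$sub[[nm]] <- rm$unit
    mc[[i]] <- rm$cache
    h <- rm$y
  }
  cat_in <- tensor_cat(list(h, r2$y))
  r3 <- unit_fwd(u$sub$cv3, cat_in, training); u$sub$cv3 <- r3$unit
  list(y = r3$y,
       cache = list(c1 = r1$cache, c2 = r2$cache, c3 = r3$cache, m = mc,
                    split = c(dim(h)[2], dim(r2$y)[2])),
       unit = u)
}

c3_bwd <- function(u, cache, gy) {
  b3 <- unit_bwd(u$sub$cv3, cache$c3, gy)
  gs <- tensor_split(b3$gx, cache$split)
  gh <- gs[[1]]
  gpar_m <- vector("list", u$cfg$n)
  for (i in rev(seq_len(u$cfg$n))) {
    bm <- unit_bwd(u$sub[[paste0("m", i)]], cache$m[[i]], gh)
    gpar_m[[i]] <- bm$gpar
    gh <- bm$gx
  }
  b1 <- unit_bwd(u$sub$cv1, cache$c1, gh)
  b2 <- unit_bwd(u$sub$cv2, cache$c2, gs[[2]])
  sub <- c(list(cv1 = b1$gpar, cv2 = b2$gpar, cv3 = b3$gpar),
           setNames(gpar_m, paste0("m", seq_len(u$cfg$n))))
  list(gx = b1$gx + b2$gx, gpar = list(sub = sub))
}

# SPPF: 1x1 reduce, three chained 5x5 stride-1 max pools, concat, 1x1 expand.
init_sppf <- function(c1, c2, k = 5) {
  ch <- max(2L, c1 %/% 2L)
  list(cfg = list(type = "sppf", k = k),
       sub = list(cv1 = init_cbs(c1, ch, 1), cv2 = init_cbs(4L * ch, c2, 1)))
}

sppf_fwd <- function(u, x, training = TRUE) {
  k <- u$cfg$k
  r1 <- unit_fwd(u$sub$cv1, x, training); u$sub$cv1 <- r1$unit
  p1 <- cpp_maxpool_fw(r1$y, k, 1L, k %/% 2L)
  p2 <- cpp_maxpool_fw(p1$y, k, 1L, k %/% 2L)
  p3 <- cpp_maxpool_fw(p2$y, k, 1L, k %/% 2L)
  cat_in <- tensor_cat(list(r1$y, p1$y, p2$y, p3$y))
  r2 <- unit_fwd(u$sub$cv2, cat_in, training); u$sub$cv2 <- r2$unit
  list(y = r2$y,
       cache = list(c1 = r1$cache, c2 = r2$cache, am = list(p1$argmax,
                    p2$argmax, p3$argmax), d = dim(r1$y)),
       unit = u)
}

sppf_bwd <- function(u, cache, gy) {
  k <- u$cfg$k
  b2 <- unit_bwd(u$sub$cv2, cache$c2, gy)
  ch <- cache$d[2]
  gs <- tensor_split(b2$gx, rep(ch, 4))
  g3 <- cpp_maxpool_bw(cache$am[[3]], gs[[4]], as.integer(cache$d))
  g2 <- cpp_maxpool_bw(cache$am[[2]], gs[[3]] + g3, as.integer(cache$d))
  g1 <- cpp_maxpool_bw(cache$am[[1]], gs[[2]] + g2, as.integer(cache$d))
  b1 <- unit_bwd(u$sub$cv1, cache$c1, gs[[1]] + g1)
  list(gx = b1$gx, gpar = list(sub = list(cv1 = b1$gpar, cv2 = b2$gpar)))
}

tensor_cat <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[2], 0)
  out <- array(0, c(d[1], sum(cs), d[3], d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, at + seq_len(cs[i]), , ] <- xs[[i]]
    at <- at + cs[i]
  }
  out
}

tensor_split <- function(x, cs) {
  at <- 0L
  out <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    out[[i]] <- x[, at + seq_len(cs[i]), , , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

unit_fwd <- function(u, x, training = TRUE) {
  switch(u$cfg$type,
         cbs = cbs_fwd(u, x, training),
         bottleneck = bottleneck_fwd(u, x, training),
         c3 = c3_fwd(u, x, training),
         sppf = sppf_fwd(u, x, training),
         se = se_unit_fwd(u, x, training),
         caaft = caaft_unit_fwd(u, x, training),
         arconv = arconv_unit_fwd(u, x, training),
         stop("unknown unit type: ", u$cfg$type))
}

unit_bwd <- function(u, cache, gy) {
  switch(u$cfg$type,
         cbs = cbs_bwd(u, cache, gy),
         bottleneck = bottleneck_bwd(u, cache, gy),
         c3 = c3_bwd(u, cache, gy),
         sppf = sppf_bwd(u, cache, gy),
         se = se_unit_bwd(u, cache, gy),
         caaft = caaft_unit_bwd(u, cache, gy),
         arconv = arconv_unit_bwd(u, cache, gy),
         stop("unknown unit type: ", u$cfg$type))
}
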