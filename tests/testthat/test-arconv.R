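test_that("odd kernel sizes follow the floor-and-decrement rule", {
  expect_identical(kernel_size(4), 3L)
  expect_identical(kernel_size(5), 5L)
  expect_identical(kernel_size(1), 1L)
  expect_identical(kernel_size(0.4), 1L)
  expect_identical(kernel_size(6.9), 5L)
  expect_identical(kernel_size(7), 7L)
  expect_error(kernel_size(0), "positive")
  expect_error(kernel_size(-2), "positive")
})

test_that("offset grids scale the integer grid by the predicted extents", {
  # h0 = k_h, w0 = k_w recovers the standard convolution grid
  R <- build_offsets(3, 3, 3, 3)
  G <- cbind(rep(-1:1, each = 3), rep(-1:1, times = 3))
  expect_equal(unname(R), unname(G) * 1.0)
  # single-point kernel
  expect_equal(unname(build_offsets(5, 2, 1, 1)), matrix(0, 1, 2))
  # doubled extent doubles the row spacing
  R2 <- build_offsets(6, 3, 3, 3)
  expect_equal(R2[, 1], G[, 1] * 2)
  expect_equal(R2[, 2], G[, 2])
  expect_error(build_offsets(3, 3, 2, 3), "odd")
  # loop-built oracle on 100 random cases
  set.seed(1)
  for (i in 1:100) {
    kh <- sample(c(1, 3, 5, 7), 1); kw <- sample(c(1, 3, 5, 7), 1)
    h0 <- runif(1, 0.5, 10); w0 <- runif(1, 0.5, 10)
    expect_equal(build_offsets(h0, w0, kh, kw),
                 oracle_offsets(h0, w0, kh, kw), tolerance = 1e-6)
  }
})

test_that("bilinear sampling interpolates with zero padding", {
  x <- feature_map(1, 1, 4, 4)
  x[1, 1, , ] <- matrix(1:16, 4, 4, byrow = TRUE)
  # integer positions return the stored value
  expect_equal(bilinear_sample(x, cbind(2, 3))[1, 1, 1], x[1, 1, 3, 4])
  # midpoint of 4 pixels with values 0,0,2,2 is their mean
  xm <- feature_map(1, 1, 2, 2)
  xm[1, 1, 2, ] <- 2
  expect_equal(bilinear_sample(xm, cbind(0.5, 0.5))[1, 1, 1], 1)
  # far outside the map: zero
  expect_equal(bilinear_sample(x, cbind(-5, -5))[1, 1, 1], 0)
  # 100 random positions vs 4-neighbour weighted-sum oracle
  set.seed(2)
  xr <- feature_map(2, 3, 6, 7, sd = 1)
  pos <- cbind(runif(100, -1.5, 6.5), runif(100, -1.5, 7.5))
  expect_equal(bilinear_sample(xr, pos), oracle_bilinear(xr, pos),
               tolerance = 1e-6)
})

test_that("predicted height/width fields respect their sigmoid bounds", {
  set.seed(3)
  u <- init_arconv(4, 4, a = 6, b = 1)
  x <- feature_map(2, 4, 8, 8, sd = 2)
  hw <- predict_hw(x, u)
  expect_true(all(hw$h_map > 1 & hw$h_map < 7))
  expect_true(all(hw$w_map > 1 & hw$w_map < 7))
  expect_equal(dim(hw$h_map)[3:4], dim(x)[3:4])
  expect_gt(hw$h_bar, 0)
  # zero subnet output: field = a * 0.5 + b exactly
  u0 <- u
  u0$sub$f1h$par$w[] <- 0
  u0$sub$f1h$par$b[] <- 0
  hw0 <- predict_hw(x, u0)
  expect_equal(as.vector(hw0$h_map), rep(6 * 0.5 + 1, length(hw0$h_map)))
  # saturated subnet output approaches the upper bound
  us <- u
  us$sub$f1h$par$w[] <- 0
  us$sub$f1h$par$b[] <- 50
  expect_equal(max(abs(predict_hw(x, us)$h_map - 7)), 0, tolerance = 1e-3)
  expect_error(init_arconv(4, 4, a = -1), "positive")
})

test_that("forcing the standard grid reduces to ordinary convolution", {
  set.seed(4)
  for (rep in 1:20) {
    c1 <- sample(2:4, 1); c2 <- sample(2:4, 1)
    u <- init_arconv(c1, c2, a = 6, b = 1)
    # force h = w = 3 everywhere: sigmoid(t) = 1/3 -> t = log(1/2)
    for (nm in c("f1h", "f2h")) {
      u$sub[[nm]]$par$w[] <- 0
      u$sub[[nm]]$par$b[] <- log(0.5)
    }
    # M and B subnets are identity-initialized (M = 1, B = 0) already
    x <- feature_map(1, c1, 7, 8, sd = 1)
    y <- arconv_forward(x, u)
    sk3 <- teabloom:::arconv_sk_window(u$par$sk, 3, 3)
    y0 <- teabloom:::cpp_conv2d_fw(x, sk3, rep(0, c2), 1L, 1L)
    # interior pixels only: border handling differs only by padding site
    expect_equal(y[, , 2:6, 2:7], y0[, , 2:6, 2:7], tolerance = 1e-5)
  }
})

test_that("the sampling map uses exactly k_h * k_w points", {
  set.seed(5)
  u <- init_arconv(3, 2)
  x <- feature_map(1, 3, 6, 6, sd = 1)
  r <- teabloom:::arconv_unit_fwd(u, x, training = FALSE)
  expect_equal(dim(r$cache$S)[3], r$cache$kh * r$cache$kw)
  expect_equal(dim(r$y), c(1, 2, 6, 6))
  # affine dominance: M = 0 makes the output equal B
  u0 <- u
  u0$sub$mnet$par$b[] <- 0
  rb <- teabloom:::unit_fwd(u0$sub$bnet, x, FALSE)$y
  expect_equal(arconv_forward(x, u0), rb, tolerance = 1e-12)
  # zero input with B = 0 gives zero output
  z <- feature_map(1, 3, 6, 6)
  expect_lt(max(abs(arconv_forward(z, u))), 1e-12)
})

test_that("the output is differentiable w.r.t. input and kernel", {
  set.seed(6)
  u <- init_arconv(1, 1, subnet_width = 4)
  x <- feature_map(1, 1, 5, 5, sd = 1)
  fw <- teabloom:::arconv_unit_fwd(u, x, training = TRUE)
  gy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- teabloom:::arconv_unit_bwd(fw$unit, fw$cache, gy)
  f <- function(xx) sum(teabloom:::arconv_unit_fwd(u, xx, TRUE)$y * gy)
  eps <- 1e-5
  idx <- sample(length(x), 6)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal((f(xp) - f(xm)) / (2 * eps), bw$gx[i], tolerance = 1e-3)
  }
  fsk <- function(sk) {
    uu <- u; uu$par$sk <- sk
    sum(teabloom:::arconv_unit_fwd(uu, x, TRUE)$y * gy)
  }
  for (i in sample(length(u$par$sk), 6)) {
    sp <- u$par$sk; sp[i] <- sp[i] + eps
    sm <- u$par$sk; sm[i] <- sm[i] - eps
    expect_equal((fsk(sp) - fsk(sm)) / (2 * eps), bw$gpar$par$sk[i],
                 tolerance = 1e-3)
  }
})
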