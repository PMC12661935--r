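test_that("squeeze-and-excitation rescales channels by a (0,1) gate", {
  set.seed(1)
  p <- se_params(8, reduction_ratio = 4)
  # zero input stays zero
  x0 <- feature_map(2, 8, 5, 6)
  expect_equal(se_forward(x0, p), x0, ignore_attr = TRUE)
  # large positive bias before the sigmoid opens every gate
  p1 <- p
  p1$w2[] <- 0
  p1$b2[] <- 40
  x <- feature_map(2, 8, 5, 6, sd = 1)
  expect_equal(se_forward(x, p1), x, ignore_attr = TRUE, tolerance = 1e-6)
  # gates lie strictly in (0, 1)
  g <- attr(se_forward(x, p), "gate")
  expect_true(all(g > 0 & g < 1))
  # brute-force per-channel rescale oracle on random instances
  for (i in 1:25) {
    xi <- feature_map(2, 8, 4, 3, sd = 1)
    yi <- se_forward(xi, p)
    gi <- attr(yi, "gate")
    yo <- xi
    for (n in 1:2) for (c in 1:8) yo[n, c, , ] <- xi[n, c, , ] * gi[n, c]
    expect_equal(yi, yo, ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(se_forward(array(1, c(2, 3)), p), "4-d")
})

test_that("coordinate-attention pooling matches the directional means", {
  # constant map: every descriptor entry equals the constant
  xc <- array(3.5, c(1, 2, 4, 6))
  d <- ca_pool(xc)
  expect_equal(dim(d$z_h), c(1, 2, 4, 1))
  expect_equal(dim(d$z_w), c(1, 2, 1, 6))
  expect_true(all(abs(d$z_h - 3.5) < 1e-12), all(abs(d$z_w - 3.5) < 1e-12))
  # single spike at (h0, w0): z_h[h0] = 1/W, z_w[w0] = 1/H
  xs <- feature_map(1, 1, 4, 6)
  xs[1, 1, 3, 2] <- 1
  ds <- ca_pool(xs)
  expect_equal(as.vector(ds$z_h[1, 1, , 1]), c(0, 0, 1 / 6, 0))
  expect_equal(as.vector(ds$z_w[1, 1, 1, ]), c(0, 1 / 4, 0, 0, 0, 0))
  # double-loop oracle on 100 random instances
  set.seed(2)
  for (i in 1:100) {
    xi <- feature_map(sample(1:2, 1), sample(1:4, 1), sample(1:5, 1),
                      sample(1:5, 1), sd = 1)
    di <- ca_pool(xi)
    oi <- oracle_ca_pool(xi)
    expect_equal(di$z_h, oi$z_h, tolerance = 1e-6)
    expect_equal(di$z_w, oi$z_w, tolerance = 1e-6)
  }
})

test_that("coordinate-attention reweighting applies the two 1D profiles", {
  set.seed(3)
  C <- 6
  p <- ca_params(C, reduction = 2)
  x <- feature_map(2, C, 4, 5, sd = 1)
  d <- ca_pool(x)
  # attentions forced fully open: identity
  p1 <- p
  p1$wh[] <- 0; p1$bh[] <- 40
  p1$ww[] <- 0; p1$bw[] <- 40
  expect_equal(ca_reweight(x, d, p1), x, ignore_attr = TRUE)
  # attentions forced closed: output vanishes
  p0 <- p
  p0$wh[] <- 0; p0$bh[] <- -40
  p0$ww[] <- 0; p0$bw[] <- -40
  expect_lt(max(abs(ca_reweight(x, d, p0))), 1e-12)
  # loop oracle applying the extracted profiles, 100 random instances
  for (i in 1:100) {
    xi <- feature_map(sample(1:2, 1), C, sample(2:5, 1), sample(2:5, 1),
                      sd = 1)
    di <- ca_pool(xi)
    yi <- ca_reweight(xi, di, p)
    yo <- oracle_reweight(xi, attr(yi, "a_h"), attr(yi, "a_w"))
    expect_equal(yi, yo, ignore_attr = TRUE, tolerance = 1e-6)
    a <- teabloom:::ca_attention(di, p)
    expect_true(all(a$a_h > 0 & a$a_h < 1))
    expect_true(all(a$a_w > 0 & a$a_w < 1))
  }
  expect_error(ca_reweight(feature_map(1, C, 3, 3), d, p), "shapes")
})

test_that("the attention-free transformer obeys its gating contract", {
  set.seed(4)
  d <- 4
  p <- aft_params(d)
  x <- matrix(rnorm(5 * d), 5, d)
  # output gate forced shut: zero output
  p0 <- p
  p0$wq[] <- 0; p0$bq[] <- -40
  expect_lt(max(abs(aft_forward(x, p0))), 1e-12)
  # T = 1, identity non-linearities, sum pooling: Y = Q' * K' * V'
  pid <- aft_params(d, sigma_q = "identity", sigma_k = "identity",
                    pool = "sum")
  x1 <- matrix(rnorm(d), 1, d)
  q1 <- x1 %*% pid$wq; k1 <- x1 %*% pid$wk; v1 <- x1 %*% pid$wv
  expect_equal(aft_forward(x1, pid), q1 * k1 * v1, tolerance = 1e-12)
  # element-wise loop oracle on 100 random instances (default gates)
  for (i in 1:100) {
    T <- sample(1:7, 1)
    xi <- matrix(rnorm(T * d), T, d)
    expect_equal(aft_forward(xi, p), oracle_aft(xi, p), tolerance = 1e-6)
  }
  expect_error(aft_forward(matrix(0, 3, 2), p), "dimension mismatch")
})

test_that("pooled context is invariant to sequence accumulation order", {
  set.seed(5)
  p <- aft_params(3)
  x <- matrix(rnorm(30), 10, 3)
  y <- aft_forward(x, p)
  for (i in 1:10) {
    perm <- sample(10)
    yp <- aft_forward(x[perm, ], p)
    # permutation equivariance: row t of y appears at its permuted place
    expect_equal(yp, y[perm, ], tolerance = 1e-6)
  }
})

test_that("the combined CA+AFT block preserves shape and composes its parts", {
  set.seed(6)
  u <- init_caaft(8, reduction = 2)
  x <- feature_map(2, 8, 16, 16, sd = 1)
  y <- caaft_forward(x, u)
  expect_equal(dim(y), c(2, 8, 16, 16))
  # swapped ablation order preserves shape but changes the output
  y_swap <- caaft_forward(x, u, ca_first = FALSE)
  expect_equal(dim(y_swap), dim(y))
  expect_gt(max(abs(y_swap - y)), 0)
  # AFT gate shut leaves only the residual (CA-reweighted) pathway; with
  # CA attentions forced open this is the identity
  uf <- u
  uf$par$wh[] <- 0; uf$par$bh[] <- 40
  uf$par$ww[] <- 0; uf$par$bw[] <- 40
  uf$par$wq[] <- 0; uf$par$bq[] <- -40
  expect_equal(caaft_forward(x, uf), x, ignore_attr = TRUE,
               tolerance = 1e-8)
  # composition oracle: CA reweight + per-image AFT over the flattened
  # sequence (height fastest), restored and added residually
  small <- feature_map(1, 4, 3, 4, sd = 1)
  us <- init_caaft(4, reduction = 2)
  xca <- ca_reweight(small, ca_pool(small), us$par)
  seqm <- matrix(aperm(array(xca, dim(small)[2:4]), c(2, 3, 1)), 12, 4)
  out <- oracle_aft(seqm, us$par)
  expected <- array(xca, dim(small))
  expected[1, , , ] <- expected[1, , , ] +
    aperm(array(out, c(3, 4, 4)), c(3, 1, 2))
  expect_equal(caaft_forward(small, us), expected, ignore_attr = TRUE,
               tolerance = 1e-6)
})
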