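test_that("the weighted total loss and confidence score follow their formulas", {
  expect_equal(total_loss(1, 1, 1, 1, 1, 1), 3)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(2, 0, 0, w_box = 0.05), 0.1)
  expect_error(total_loss(1, 1, 1, w_box = -1), "non-negative")
  expect_equal(confidence_score(1, 1, 1), 1)
  expect_equal(confidence_score(0.5, 0.5, 0.5), 0.125)
  expect_equal(confidence_score(0, 0.9, 0.9), 0)
  expect_error(confidence_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("complete-IoU gradients match finite differences", {
  set.seed(1)
  p <- cbind(runif(20, 2, 8), runif(20, 2, 8), runif(20, 1, 4),
             runif(20, 1, 4))
  t <- cbind(runif(20, 2, 8), runif(20, 2, 8), runif(20, 1, 4),
             runif(20, 1, 4))
  ci <- teabloom:::ciou_rows(p, t)
  expect_true(all(ci <= 1 + 1e-12))
  expect_equal(teabloom:::ciou_rows(t, t), rep(1, 20), tolerance = 1e-6)
  g <- teabloom:::ciou_grad(p, t)
  for (k in 1:4) {
    pp <- p; pp[, k] <- pp[, k] + 1e-6
    pm <- p; pm[, k] <- pm[, k] - 1e-6
    fd <- (teabloom:::ciou_rows(pp, t) - teabloom:::ciou_rows(pm, t)) / 2e-6
    expect_equal(g[, k], fd, tolerance = 1e-3)
  }
})

test_that("target assignment respects the anchor-ratio filter and grid", {
  cfg <- model_config(input_size = 160, width_multiple = 0.125)
  # an object far larger than any anchor at a scale is not assigned there
  lab <- matrix(c(1, 0, 0.5, 0.5, 0.9, 0.9), 1)
  tg <- teabloom:::build_targets(lab, cfg)
  small_scale <- tg[[1]]
  expect_equal(nrow(small_scale), 0)
  # a typical object lands in the grid with its centre cell included
  lab2 <- matrix(c(1, 2, 0.52, 0.48, 0.1, 0.12), 1)
  tg2 <- teabloom:::build_targets(lab2, cfg)
  all_rows <- do.call(rbind, tg2)
  expect_gt(nrow(all_rows), 0)
  for (s in 1:3) {
    r <- tg2[[s]]
    if (!nrow(r)) next
    grid <- 160 / cfg$strides[s]
    expect_true(all(r$gi >= 0 & r$gi < grid & r$gj >= 0 & r$gj < grid))
    expect_true(all(floor(r$tx) %in% c(r$gi - 1, r$gi, r$gi + 1)))
    expect_true(all(r$cls == 2))
  }
  # empty labels produce empty assignments
  tg0 <- teabloom:::build_targets(matrix(numeric(0), 0, 6), cfg)
  expect_true(all(vapply(tg0, nrow, 0L) == 0))
})

test_that("non-maximum suppression keeps the right survivors", {
  one <- data.frame(class_id = 0, x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                    confidence = 0.9)
  expect_equal(nrow(nms(one, 0.45, 0.25)), 1)
  # identical duplicate: higher confidence survives
  two <- rbind(one, transform(one, confidence = 0.8))
  kept <- nms(two, 0.45, 0.25)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)
  # disjoint boxes both survive
  disj <- rbind(one, data.frame(class_id = 0, x1 = 50, y1 = 50, x2 = 60,
                                y2 = 60, confidence = 0.3))
  expect_equal(nrow(nms(disj, 0.45, 0.25)), 2)
  # different classes are not suppressed unless agnostic
  cross <- rbind(one, transform(one, class_id = 1, confidence = 0.8))
  expect_equal(nrow(nms(cross, 0.45, 0.25)), 2)
  expect_equal(nrow(nms(cross, 0.45, 0.25, agnostic = TRUE)), 1)
  # below the confidence threshold: dropped
  expect_equal(nrow(nms(one, 0.45, 0.95)), 0)
  expect_equal(nrow(nms(one[0, ], 0.45, 0.25)), 0)
  expect_error(nms(one, 1.5, 0.25), "\\[0, 1\\]")
})

test_that("suppression output is a subset and idempotent", {
  set.seed(2)
  for (rep in 1:10) {
    n <- 30
    det <- data.frame(class_id = sample(0:2, n, TRUE),
                      x1 = runif(n, 0, 80), y1 = runif(n, 0, 80))
    det$x2 <- det$x1 + runif(n, 5, 30)
    det$y2 <- det$y1 + runif(n, 5, 30)
    det$confidence <- runif(n)
    k1 <- nms(det, 0.45, 0.1)
    expect_true(all(apply(k1, 1, paste, collapse = "|") %in%
                      apply(det, 1, paste, collapse = "|")))
    k2 <- nms(k1, 0.45, 0.1)
    expect_equal(k1, k2, ignore_attr = TRUE)
    # survivors of the same class never overlap above the threshold
    for (cl in unique(k1$class_id)) {
      b <- as.matrix(k1[k1$class_id == cl, c("x1", "y1", "x2", "y2")])
      if (nrow(b) < 2) next
      M <- teabloom:::iou_matrix(b, b)
      diag(M) <- 0
      expect_lte(max(M), 0.45)
    }
  }
})
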