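test_that("IoU handles identical, disjoint and partially overlapping boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  # overlap 1x1 = 1, union 4 + 4 - 1 = 7
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  # rasterized-area cross-check on a fine grid
  grid <- expand.grid(x = seq(0.005, 3.995, by = 0.01),
                      y = seq(0.005, 3.995, by = 0.01))
  inA <- grid$x > 0 & grid$x < 2 & grid$y > 0 & grid$y < 2
  inB <- grid$x > 1 & grid$x < 3 & grid$y > 1 & grid$y < 3
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               sum(inA & inB) / sum(inA | inB), tolerance = 1e-3)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "positive")
  # symmetry on random boxes
  set.seed(1)
  for (i in 1:20) {
    a <- c(sort(runif(2, 0, 5)), sort(runif(2, 0, 5)))[c(1, 3, 2, 4)]
    b <- c(sort(runif(2, 0, 5)), sort(runif(2, 0, 5)))[c(1, 3, 2, 4)]
    expect_equal(iou(a, b), iou(b, a))
  }
})

test_that("greedy matching produces the documented confusion counts", {
  gt <- data.frame(x1 = c(0, 10), y1 = c(0, 10), x2 = c(5, 15),
                   y2 = c(5, 15))
  # perfect predictions
  det <- cbind(gt, confidence = c(0.9, 0.8))
  m <- match_detections(det, gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(2, 0, 0))
  # no predictions
  m <- match_detections(det[0, ], gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(0, 0, 2))
  # two detections on one truth: one TP one FP
  det2 <- data.frame(x1 = c(0, 0.2), y1 = c(0, 0.2), x2 = c(5, 5.2),
                     y2 = c(5, 5.2), confidence = c(0.9, 0.8))
  m <- match_detections(det2, gt[1, ], 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 1, 0))
  expect_equal(m$matched, c(1L, NA_integer_))
})

test_that("greedy matching agrees with exhaustive optimal matching on small cases", {
  set.seed(42)
  optimal_tp <- function(det, gt, thr) {
    nd <- nrow(det); ng <- nrow(gt)
    M <- teabloom:::iou_matrix(as.matrix(det[, 1:4]), as.matrix(gt[, 1:4]))
    best <- 0
    assign <- function(i, used, tp) {
      if (i > nd) { best <<- max(best, tp); return(invisible()) }
      assign(i + 1, used, tp)
      for (j in seq_len(ng))
        if (!used[j] && M[i, j] >= thr) {
          used[j] <- TRUE
          assign(i + 1, used, tp + 1)
          used[j] <- FALSE
        }
    }
    assign(1, rep(FALSE, ng), 0)
    best
  }
  agree <- 0; total <- 0
  for (rep in 1:30) {
    nd <- sample(0:4, 1); ng <- sample(1:4, 1)
    det <- data.frame(x1 = runif(nd, 0, 6), y1 = runif(nd, 0, 6))
    det$x2 <- det$x1 + runif(nd, 1, 4); det$y2 <- det$y1 + runif(nd, 1, 4)
    det$confidence <- runif(nd)
    gt <- data.frame(x1 = runif(ng, 0, 6), y1 = runif(ng, 0, 6))
    gt$x2 <- gt$x1 + runif(ng, 1, 4); gt$y2 <- gt$y1 + runif(ng, 1, 4)
    m <- match_detections(det, gt, 0.3)
    o <- if (nd) optimal_tp(det, gt, 0.3) else 0
    total <- total + 1
    if (m$TP == o) agree <- agree + 1
    expect_lte(m$TP, o)  # greedy can never beat optimal
  }
  expect_gte(agree / total, 0.9)
})

test_that("precision, recall and F1 follow the confusion-matrix formulas", {
  c1 <- list(TP = 8, FP = 2, FN = 3)
  expect_equal(precision(c1), 0.8)
  expect_equal(recall(c1), 8 / 11)
  expect_equal(f1(0.5, 0.5), 0.5)        # harmonic mean of equals
  expect_equal(precision(list(TP = 0, FP = 0, FN = 5)), 0)
  expect_equal(f1(0, 0), 0)
  # harmonic-mean bounds
  set.seed(2)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    expect_lte(f1(p, r), (p + r) / 2 + 1e-12)
    expect_lte(f1(p, r), 2 * min(p, r) + 1e-12)
  }
})

test_that("average precision integrates the exact precision envelope", {
  # perfect detector: all TPs before any FP, full recall
  curve <- pr_curve(c(0.9, 0.8, 0.7), c(TRUE, TRUE, TRUE), 3)
  expect_identical(average_precision(curve), 1)
  # zero TPs
  curve0 <- pr_curve(c(0.9, 0.8), c(FALSE, FALSE), 3)
  expect_equal(average_precision(curve0), 0)
  # scripted 5-detection, 3-truth case: TP FP TP FP TP by confidence
  conf <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  tp <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  ap <- average_precision(pr_curve(conf, tp, 3))
  expect_equal(ap, oracle_ap(conf, tp, 3), tolerance = 1e-12)
  expect_equal(ap, (1 + 2 / 3 + 3 / 5) / 3, tolerance = 1e-12)
  # oracle equivalence on 100 random sweeps
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    conf <- runif(n)
    tp <- runif(n) < 0.6
    nt <- max(sum(tp), sample(1:6, 1))
    expect_equal(average_precision(pr_curve(conf, tp, nt)),
                 oracle_ap(conf, tp, nt), tolerance = 1e-6)
  }
  # tie invariance: equal confidences keep the documented input-order rule
  cv <- pr_curve(c(0.5, 0.5, 0.5), c(TRUE, FALSE, TRUE), 2)
  expect_equal(average_precision(cv), oracle_ap(c(0.5, 0.5, 0.5),
                                                c(TRUE, FALSE, TRUE), 2))
})

test_that("mAP averages per-class AP and skips absent classes", {
  expect_equal(mean_ap(c(0.7)), 0.7)
  expect_equal(mean_ap(c(1, 0, 0.5)), 0.5)
  expect_equal(mean_ap(c(1, NA, 0.5)), 0.75)
})

test_that("R-squared matches its defining formula", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 2, 9)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(9, 9, 9)), 0)
  expect_error(r_squared(c(2, 2), c(1, 2)), "variance")
})

test_that("accuracy is the trace over the total of a confusion matrix", {
  expect_equal(accuracy(diag(c(3, 4, 5))), 1)
  expect_equal(accuracy(matrix(1, 5, 5)), 0.2)
  expect_equal(accuracy(matrix(c(8, 3, 2, 7), 2, 2)), 0.75)
  expect_equal(accuracy(list(TP = 8, TN = 7, FP = 2, FN = 3)), 0.75)
})

test_that("dataset-level evaluation sweeps confidences per class", {
  truth <- data.frame(image = c("a", "a", "b"), class_id = c(0, 1, 0),
                      x1 = c(0, 10, 0), y1 = c(0, 10, 0),
                      x2 = c(5, 15, 5), y2 = c(5, 15, 5))
  pred <- cbind(truth, confidence = 1)
  ev <- evaluate_detections(pred, truth, classes = 0:1)
  expect_equal(ev$mAP, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(map_range(pred, truth, classes = 0:1), 1)
})
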