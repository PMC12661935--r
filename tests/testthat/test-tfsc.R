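test_that("softmax is stable, normalized and shift-invariant", {
  expect_equal(softmax(rep(3, 5)), rep(0.2, 5))
  p <- softmax(c(1000, 0))
  expect_equal(p, c(1, 0), tolerance = 1e-12)
  expect_false(any(is.nan(p)))
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:30) {
    o <- rnorm(5, sd = 10^runif(1, 0, 4))
    expect_equal(sum(softmax(o)), 1, tolerance = 1e-6)
    expect_equal(softmax(o), softmax(o + 123.4), tolerance = 1e-9)
  }
})

make_records <- function() {
  sp <- season_spec(accession_id = "A", season_start = as.Date("2023-10-01"),
                    noise_dispersion = 0, seed = 1)
  r1 <- generate_season(sp, sp$season_start + seq(0, 60, 3), replicates = 3)
  sp2 <- season_spec(accession_id = "A", season_start = as.Date("2024-10-05"),
                     noise_dispersion = 0, seed = 2)
  r2 <- generate_season(sp2, sp2$season_start + seq(0, 60, 3),
                        replicates = 3)
  rbind(r1, r2)
}

test_that("stage-dataset construction groups in threes and averages", {
  rec <- data.frame(accession = "X", date = as.Date("2023-11-01"),
                    bud = c(2, 4, 6, 1, 3, 5), b_flower = 10, w_flower = 0,
                    stage = "MFS")
  # quality filter would drop X (median total 13 >= 3, so kept)
  ds <- build_stage_dataset(rbind(rec,
    data.frame(accession = "Y", date = as.Date("2024-11-01"),
               bud = 20, b_flower = 20, w_flower = 5, stage = "MFS")),
    min_median_total = 3, seed = 1)
  first_year <- rbind(ds$train, ds$val)
  # 6 same-accession-date records -> 2 averaged samples
  expect_equal(nrow(first_year), 2)
  expect_setequal(first_year$bud, c(mean(c(2, 4, 6)), mean(c(1, 3, 5))))
  # the single year-2 record forms the (here empty after grouping) test set
  expect_equal(nrow(ds$test), 0)  # 1 record < group of 3 is dropped
  # an accession with all-zero counts is excluded entirely
  zero <- data.frame(accession = "Z", date = as.Date("2023-11-01"),
                     bud = 0, b_flower = 0, w_flower = 0, stage = "IFS")
  ds2 <- build_stage_dataset(rbind(rec, zero[rep(1, 6), ]), seed = 1)
  expect_false(any(c(ds2$train$accession, ds2$val$accession) == "Z"))
  expect_error(build_stage_dataset(zero), "quality filter")
})

test_that("year-1 samples split 8:2 and year-2 samples form the test set", {
  rec <- make_records()
  ds <- build_stage_dataset(rec, seed = 3)
  n1 <- nrow(ds$train) + nrow(ds$val)
  expect_equal(nrow(ds$train), floor(0.8 * n1))
  expect_true(all(format(ds$test$date, "%Y") == "2024"))
  expect_true(all(format(rbind(ds$train, ds$val)$date, "%Y") == "2023"))
  expect_true(all(ds$test$time >= 0 & ds$test$time <= 1))
})

test_that("zero-epoch training returns the initialized net unchanged", {
  rec <- make_records()
  ds <- build_stage_dataset(rec, seed = 3)
  net0 <- train_tfsc(ds$train, epochs = 0, seed = 7)
  ref <- teabloom:::with_seed(7, teabloom:::init_tfsc_net())
  expect_equal(net0$net$W, ref$W)
  expect_equal(nrow(net0$history), 0)
  # seven layers: six hidden + output
  expect_length(net0$net$W, 7)
})

test_that("training refuses single-class data and is deterministic", {
  rec <- make_records()
  ds <- build_stage_dataset(rec, seed = 3)
  one <- ds$train[ds$train$stage == ds$train$stage[1], , drop = FALSE]
  expect_error(train_tfsc(one, epochs = 1), "single stage")
  f1 <- train_tfsc(ds$train, epochs = 2, seed = 9)
  f2 <- train_tfsc(ds$train, epochs = 2, seed = 9)
  expect_equal(f1$history$loss[1], f2$history$loss[1], tolerance = 1e-9)
})

test_that("noiseless seasons are learned almost perfectly", {
  recs <- do.call(rbind, lapply(1:12, function(a) {
    out <- NULL
    for (y in 1:2) {
      sp <- season_spec(accession_id = sprintf("A%02d", a),
                        season_start = as.Date(sprintf("%d-10-01", 2022 + y))
                        + a %% 7,
                        peak_day = 25 + (a %% 10), peak_amplitude = 40 + 5 * a,
                        noise_dispersion = 0, seed = a * 10 + y)
      out <- rbind(out, generate_season(sp, sp$season_start + seq(0, 60, 2),
                                        replicates = 3))
    }
    out
  }))
  ds <- build_stage_dataset(recs, seed = 5)
  fit <- train_tfsc(ds$train, val = ds$val, epochs = 80, seed = 5)
  expect_gte(tail(fit$history$val_acc, 1), 0.95)
})

test_that("stage prediction reports probabilities and breaks ties low", {
  rec <- make_records()
  ds <- build_stage_dataset(rec, seed = 3)
  fit <- train_tfsc(ds$train, epochs = 5, seed = 1)
  pr <- predict_stage(fit, ds$val)
  expect_equal(nrow(pr), nrow(ds$val))
  probs <- as.matrix(pr[, paste0("p_", c("IFS", "EFS", "MFS", "LFS",
                                         "TFS"))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pr)), tolerance = 1e-6)
  expect_equal(pr$stage,
               c("IFS", "EFS", "MFS", "LFS", "TFS")[
                 max.col(probs, ties.method = "first")])
  # batch order stability
  pr2 <- predict_stage(fit, ds$val)
  expect_identical(pr, pr2)
})

test_that("stage evaluation tallies the confusion matrix by hand", {
  pred <- c("IFS", "EFS", "EFS", "MFS", "LFS", "TFS", "TFS", "MFS", "IFS",
            "EFS")
  true <- c("IFS", "IFS", "EFS", "MFS", "MFS", "TFS", "LFS", "LFS", "IFS",
            "MFS")
  ev <- evaluate_stages(pred, true)
  expect_equal(ev$accuracy, 0.5)
  expect_equal(dim(ev$confusion), c(5, 5))
  expect_equal(sum(ev$confusion), 10)
  expect_equal(ev$confusion["IFS", "IFS"], 2)
  expect_equal(ev$confusion["IFS", "EFS"], 1)
  # all five misclassifications here are adjacent-stage
  expect_equal(ev$adjacent_error_rate, 1)
  # all correct: diagonal, accuracy 1
  ev1 <- evaluate_stages(true, true)
  expect_equal(ev1$accuracy, 1)
  expect_true(all(ev1$confusion[upper.tri(ev1$confusion)] == 0))
  # constant prediction on balanced labels: accuracy 1/5
  bal <- rep(c("IFS", "EFS", "MFS", "LFS", "TFS"), each = 2)
  expect_equal(evaluate_stages(rep("MFS", 10), bal)$accuracy, 0.2)
})

test_that("the feature scaler is fitted on training data only", {
  rec <- make_records()
  ds <- build_stage_dataset(rec, seed = 3)
  fit <- train_tfsc(ds$train, epochs = 3, seed = 2)
  X <- teabloom:::tfsc_features(ds$train)
  expect_equal(unname(fit$scaler$mean), unname(colMeans(X)))
  expect_equal(unname(fit$scaler$sd[1]), sd(X[, 1]))
  # predictions on the test set do not depend on test-set statistics:
  # adding a shifted copy of the test rows leaves per-row outputs unchanged
  p1 <- predict_stage(fit, ds$val)
  aug <- rbind(ds$val, transform(ds$val, bud = bud * 10))
  p2 <- predict_stage(fit, aug)
  expect_identical(p1, p2[seq_len(nrow(ds$val)), ])
})

test_that("series classification averages same-date triples when available", {
  rec <- make_records()
  ds <- build_stage_dataset(rec, seed = 3)
  fit <- train_tfsc(ds$train, epochs = 3, seed = 2)
  counts3 <- data.frame(accession = "A", date = as.Date("2023-11-05"),
                        bud = c(10, 20, 30), b_flower = c(5, 5, 5),
                        w_flower = 0:2)
  out3 <- classify_stage_series(fit, counts3)
  expect_equal(nrow(out3), 1)
  expect_true(out3$averaged)
  counts1 <- counts3[1, ]
  out1 <- classify_stage_series(fit, counts1)
  expect_false(out1$averaged)
})
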