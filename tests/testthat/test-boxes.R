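test_that("normalized/pixel box conversions round-trip", {
  set.seed(3)
  b <- cbind(cx = runif(20, 0.2, 0.8), cy = runif(20, 0.2, 0.8),
             w = runif(20, 0.05, 0.3), h = runif(20, 0.05, 0.3))
  px <- xywhn_to_xyxy(b, 640, 480)
  back <- xyxy_to_xywhn(px, 640, 480)
  expect_equal(unname(back), unname(b), tolerance = 1e-12)
  expect_true(all(px[, 3] > px[, 1]), all(px[, 4] > px[, 2]))
})

test_that("tiling splits into 2x2 quadrants with correct label bookkeeping", {
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  # a box wholly inside quadrant 0 (top-left)
  boxes <- rbind(c(1, 0.25, 0.25, 0.1, 0.1))
  tiles <- tile_image(img, boxes)
  expect_length(tiles, 4)
  expect_equal(dim(tiles[[1]]$image), c(64, 64, 3))
  expect_equal(nrow(tiles[[1]]$boxes), 1)
  expect_null(tiles[[2]]$boxes)
  # normalized size doubles in the tile
  expect_equal(unname(tiles[[1]]$boxes[1, 4:5]), c(0.2, 0.2),
               tolerance = 1e-12)
  expect_equal(unname(tiles[[1]]$boxes[1, 2:3]), c(0.5, 0.5),
               tolerance = 1e-12)
  # a box centred on the vertical cut appears clipped in two tiles
  straddle <- rbind(c(0, 0.5, 0.25, 0.2, 0.1))
  tiles2 <- tile_image(img, straddle, min_visible_fraction = 0.25)
  expect_equal(nrow(tiles2[[1]]$boxes), 1)
  expect_equal(nrow(tiles2[[2]]$boxes), 1)
  expect_null(tiles2[[3]]$boxes)
  # each clipped fragment covers half the original width
  expect_equal(unname(tiles2[[1]]$boxes[1, "w"]) * 64, 0.1 * 128,
               tolerance = 1e-9)
})

test_that("tiling conserves labels when nothing straddles a cut", {
  set.seed(4)
  # boxes strictly inside quadrants
  qc <- expand.grid(cx = c(0.25, 0.75), cy = c(0.25, 0.75))
  boxes <- cbind(class = sample(0:2, 8, TRUE),
                 cx = rep(qc$cx, 2) + runif(8, -0.05, 0.05),
                 cy = rep(qc$cy, 2) + runif(8, -0.05, 0.05),
                 w = runif(8, 0.05, 0.1), h = runif(8, 0.05, 0.1))
  tiles <- tile_image(width = 256, height = 256, boxes = boxes,
                      min_visible_fraction = 0)
  total <- sum(vapply(tiles, function(t) NROW(t$boxes), 0))
  expect_equal(total, nrow(boxes))
})

test_that("size mismatch fails or resizes per the config flag", {
  img <- array(0.5, c(100, 100, 3))
  expect_error(tile_image(img, expected_size = c(128, 128)), "expected")
  tiles <- tile_image(img, expected_size = c(128, 128),
                      on_size_mismatch = "resize")
  expect_equal(dim(tiles[[1]]$image), c(64, 64, 3))
})

test_that("the reference tiling geometry matches the documented sizes", {
  # a 3280 x 2464 capture tiles into four 1640 x 1232 quadrants
  tiles <- tile_image(width = 3280, height = 2464,
                      boxes = rbind(c(0, 0.25, 0.25, 0.01, 0.01)))
  expect_length(tiles, 4)
  b <- tiles[[1]]$boxes
  expect_equal(unname(b[1, 2:3]), c(0.5, 0.5), tolerance = 1e-12)
})
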