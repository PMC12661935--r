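test_that("scene specs validate their invariants", {
  expect_error(scene_spec(class_mix = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(scene_spec(min_visible_fraction = 0), "min_visible_fraction")
  expect_s3_class(easy_scene_spec(), "scene_spec")
})

test_that("scene generation honours object counts, classes and determinism", {
  # no objects: background only, empty labels
  sc0 <- generate_scene(scene_spec(image_size = 96, n_objects = 0, seed = 1))
  expect_equal(nrow(sc0$boxes), 0)
  expect_equal(unname(sc0$counts_true), c(0L, 0L, 0L))
  # forced single class, no occlusion: exactly 10 class-0 boxes
  sc1 <- generate_scene(scene_spec(image_size = 192, n_objects = 10,
                                   class_mix = c(1, 0, 0),
                                   occlusion_rate = 0, light_spot_rate = 0,
                                   seed = 2))
  expect_equal(nrow(sc1$boxes), 10)
  expect_true(all(sc1$boxes[, "class"] == 0))
  # determinism: same spec and seed give byte-identical labels and images
  sp <- scene_spec(image_size = 96, n_objects = 6, seed = 7)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_labels(a$boxes, f1); write_labels(b$boxes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("emitted boxes are normalized with positive extents", {
  set.seed(5)
  for (s in 1:8) {
    sc <- generate_scene(scene_spec(image_size = 96, n_objects = 8,
                                    occlusion_rate = 0.4, seed = s))
    if (nrow(sc$boxes) == 0) next
    expect_true(all(sc$boxes[, 2:5] >= 0 & sc$boxes[, 2:5] <= 1))
    expect_true(all(sc$boxes[, "w"] > 0 & sc$boxes[, "h"] > 0))
  }
})

test_that("impossible placements raise a placement-failure error", {
  expect_error(generate_scene(scene_spec(image_size = 64, n_objects = 50,
                                         size_scale = 20, seed = 1)),
               "placement failure")
})

test_that("dataset splits use largest-remainder allocation", {
  expect_equal(teabloom:::split_counts(100, c(0.6, 0.2, 0.2)),
               c(60L, 20L, 20L))
  expect_equal(teabloom:::split_counts(1, c(1, 0, 0)), c(1L, 0L, 0L))
  expect_equal(sum(teabloom:::split_counts(7, c(0.6, 0.2, 0.2))), 7L)
})

test_that("generated datasets follow the layout and class mix", {
  dir <- tempfile("ds")
  sp <- scene_spec(image_size = 96, n_objects = c(3, 9),
                   class_mix = c(0.57, 0.25, 0.18), occlusion_rate = 0,
                   light_spot_rate = 0, size_scale = 2, seed = 10)
  generate_dataset(sp, 30, dir)
  tr <- teabloom:::list_split(dir, "train")
  expect_equal(nrow(tr), 18)
  expect_equal(nrow(teabloom:::list_split(dir, "val")), 6)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 30)
  expect_true(all(c("image", "split", "n_bud", "n_bloom", "n_wither")
                  %in% names(man)))
  # class-mix convergence: count emitted labels over a larger batch of
  # in-memory scenes (law of large numbers, +-5 percentage points)
  counts <- c(0, 0, 0)
  for (i in 1:150) {
    sc <- generate_scene(scene_spec(image_size = 96, n_objects = 6,
                                    class_mix = c(0.57, 0.25, 0.18),
                                    occlusion_rate = 0, light_spot_rate = 0,
                                    size_scale = 2, seed = 1000 + i))
    if (nrow(sc$boxes))
      counts <- counts + tabulate(sc$boxes[, "class"] + 1, 3)
  }
  shares <- counts / sum(counts)
  expect_true(all(abs(shares - c(0.57, 0.25, 0.18)) <= 0.05))
})
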