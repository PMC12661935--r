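test_that("head grids follow the stride arithmetic", {
  cfg <- model_config(input_size = 640, width_multiple = 0.125,
                      depth_multiple = 0.33)
  m <- build_model(cfg, seed = 1)
  fw <- model_forward(m, feature_map(1, 3, 640, 640, sd = 0.1))
  expect_equal(vapply(fw$heads, function(h) dim(h)[3], 0), c(80, 40, 20))
  expect_equal(vapply(fw$heads, function(h) dim(h)[2], 0), rep(24, 3))
  cfg2 <- model_config(input_size = 320, width_multiple = 0.125,
                       depth_multiple = 0.33)
  fw2 <- model_forward(build_model(cfg2, seed = 1),
                       feature_map(1, 3, 320, 320, sd = 0.1))
  expect_equal(vapply(fw2$heads, function(h) dim(h)[3], 0), c(40, 20, 10))
  expect_error(model_config(input_size = 100), "divisible by 32")
})

test_that("disabling the attention flags yields the baseline graph", {
  base <- build_model(model_config(input_size = 160, width_multiple = 0.125,
                                   use_se = FALSE,
                                   arconv_stages = integer(0),
                                   use_caaft = FALSE), seed = 1)
  full <- build_model(model_config(input_size = 160, width_multiple = 0.125),
                      seed = 1)
  types <- function(m) vapply(m$nodes, function(nd)
    if (is.null(nd$unit)) nd$op else nd$unit$cfg$type, "")
  expect_equal(sum(types(full) == "se"), 1)
  expect_equal(sum(types(full) == "caaft"), 1)
  expect_equal(sum(types(base) %in% c("se", "caaft")), 0)
  expect_equal(length(full$nodes), length(base$nodes) + 2)
  has_arconv <- function(u) {
    if (is.null(u)) return(FALSE)
    if (u$cfg$type == "arconv") return(TRUE)
    any(vapply(u$sub, has_arconv, TRUE))
  }
  expect_true(any(vapply(full$nodes, function(nd) has_arconv(nd$unit), TRUE)))
  expect_false(any(vapply(base$nodes, function(nd) has_arconv(nd$unit), TRUE)))
})

test_that("the full graph backward agrees with finite differences", {
  set.seed(9)
  # the adaptive-convolution kernel-size step is piecewise constant, which
  # makes full-graph finite differences unreliable near a size boundary;
  # its own gradients are checked in test-arconv.R
  cfg <- model_config(input_size = 64, width_multiple = 0.06,
                      depth_multiple = 0.33, arconv_stages = integer(0))
  m <- build_model(cfg, seed = 2)
  x <- feature_map(1, 3, 64, 64, sd = 0.5)
  f0 <- model_forward(m, x, training = TRUE)
  R <- lapply(f0$heads, function(h) array(rnorm(length(h)), dim(h)))
  lossfun <- function(mm) {
    f <- model_forward(mm, x, training = TRUE)
    sum(mapply(function(h, r) sum(h * r), f$heads, R))
  }
  gp <- teabloom:::model_backward(f0$model, x, f0, R)
  for (nodei in c(1, 9, 12)) {           # stem, SE, near-CAAFT nodes
    u <- m$nodes[[nodei]]$unit
    gg <- gp[[nodei]]
    while (is.null(u$par)) { u <- u$sub[[1]]; gg <- gg$sub[[1]] }
    nm <- names(u$par)[1]
    mp <- m; mm2 <- m
    poke <- function(mod, delta) {
      nd <- mod$nodes[[nodei]]$unit
      if (!is.null(nd$par)) nd$par[[nm]][1] <- nd$par[[nm]][1] + delta
      else nd$sub[[1]]$par[[nm]][1] <- nd$sub[[1]]$par[[nm]][1] + delta
      mod$nodes[[nodei]]$unit <- nd
      mod
    }
    # piecewise-linear activations make finite differences noisy at these
    # tiny widths; the check guards the graph wiring (a dropped or doubled
    # gradient path errs by 50-100%), so a loose relative tolerance is apt
    num <- (lossfun(poke(m, 1e-5)) - lossfun(poke(m, -1e-5))) / 2e-5
    expect_equal(num, gg$par[[nm]][1], tolerance = 0.1,
                 label = paste("node", nodei))
  }
})

test_that("anchor estimation clusters label sizes into three scales", {
  set.seed(4)
  wh <- rbind(matrix(runif(40, 5, 15), 20, 2),
              matrix(runif(40, 30, 60), 20, 2),
              matrix(runif(40, 100, 200), 20, 2))
  a <- anchors_from_labels(wh, seed = 1)
  expect_equal(dim(a), c(3, 3, 2))
  areas <- apply(a, 1, function(s) mean(s[, 1] * s[, 2]))
  expect_true(all(diff(areas) > 0))      # increasing by scale
  expect_identical(a, anchors_from_labels(wh, seed = 1))  # deterministic
})
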