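#' Scaled-down learning benchmark
#'
#' Trains a tiny detector (width multiple 0.125, 160-px input, shallow
#' depth) from scratch on a small dataset of easy synthetic scenes and
#' scores it against the generator truth: validation mAP at IoU 0.5, and
#' counting R-squared on the test split at a counting threshold calibrated
#' on the validation split. Anchors are re-estimated from the training
#' labels by k-means. This is a capability check of the training loop at
#' desk scale, not a claim about field imagery.
#'
#' @param seed global seed (dataset, initialization, shuffling)
#' @param n_images dataset size (split 6:2:2)
#' @param epochs training epochs
#' @param lr learning rate (cosine-decayed)
#' @param dir working directory for the dataset (a fresh dataset is
#'   generated per data seed under it)
#' @param data_seed seed of the scene dataset (defaults to `seed`; fixing
#'   it across runs varies only initialization/shuffling)
#' @return list with `map50`, `count_r2` (test split, validation-calibrated
#'   counting), the `counter` calibration, per-image `counts`, `fit` and
#'   `data_dir`
#' @export
run_learning_benchmark <- function(seed, n_images = 200, epochs = 40,
                                   lr = 0.02, dir = tempfile("bench"),
                                   data_seed = seed, cache_fit = FALSE) {
  data_dir <- file.path(dir, paste0("scenes_", data_seed))
  if (!dir.exists(data_dir)) {
    sp <- easy_scene_spec(seed = data_seed)
    generate_dataset(sp, n_images, data_dir)
  }
  cfg <- model_config(input_size = 160, width_multiple = 0.125,
                      depth_multiple = 0.33, use_se = FALSE,
                      arconv_stages = integer(0), use_caaft = FALSE)
  model <- build_model(cfg, seed = seed + 1L)
  labs <- list_split(data_dir, "train")
  wh <- do.call(rbind, lapply(labs$label, function(p) {
    b <- read_labels(p)
    if (nrow(b)) b[, 4:5, drop = FALSE] * cfg$input_size
  }))
  model$cfg$anchors <- anchors_from_labels(wh, seed = seed + 2L)
  fit_path <- file.path(dir, sprintf("fit_%d_%d.rds", seed, epochs))
  if (cache_fit && file.exists(fit_path)) {
    fit <- load_checkpoint(fit_path)
  } else {
    fit <- train_detector(model, data_dir, epochs = epochs, lr = lr,
                          seed = seed + 3L)
    if (cache_fit) save_checkpoint(fit, fit_path)
  }
  ev_val <- evaluate_model(fit, data_dir, "val")
  cal <- calibrate_counting(fit, data_dir, "val")
  counts <- count_with_calibration(fit, data_dir, "test", cal)
  list(map50 = ev_val$mAP50, count_r2 = attr(counts, "r2"),
       counter = cal, counts = counts,
       val = ev_val, fit = fit, data_dir = data_dir)
}
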