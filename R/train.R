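#' Train the detector
#'
#' Stochastic gradient descent with momentum on the weighted three-term
#' loss, with a short linear warm-up of the learning rate. Training is
#' deterministic given the seed (single-threaded, fixed shuffling). The
#' defaults mirror the reference training configuration (SGD, learning rate
#' 0.01, batch size 8); epochs are caller-chosen for desk-scale runs.
#'
#' @param model a `tflos_model` from [build_model()]
#' @param data_dir dataset directory in the images/labels split layout (see
#'   [generate_dataset()])
#' @param epochs number of epochs
#' @param batch_size images per batch
#' @param lr,momentum,weight_decay SGD hyperparameters
#' @param seed RNG seed controlling shuffling and augmentation
#' @param augment apply horizontal-flip augmentation
#' @param warmup_iters iterations of linear learning-rate warm-up
#' @param cosine_decay decay the learning rate along a half-cosine to 10%
#'   of `lr` over the run (sharpens late-stage box regression)
#' @param ema_decay weight decay factor of the exponential moving average
#'   of parameters kept for evaluation (0 disables; the returned model
#'   carries the averaged weights, the raw ones are kept alongside)
#' @param class_weights optional per-class multipliers on the
#'   classification loss term (class-imbalance mitigation); `"auto"`
#'   derives inverse-frequency weights from the training labels, NULL
#'   (default) disables
#' @param val_loss also compute the validation loss each epoch
#' @param verbose print per-epoch losses
#' @return a `tflos_fit` object: the trained model, the config, the seed
#'   and a per-epoch loss history
#' @export
train_detector <- function(model, data_dir, epochs = 10, batch_size = 8,
                           lr = 0.01, momentum = 0.937, weight_decay = 0,
                           seed = 0, augment = TRUE, warmup_iters = 50,
                           cosine_decay = TRUE, ema_decay = 0.995,
                           class_weights = NULL, val_loss = FALSE,
                           verbose = FALSE) {
  listing <- list_split(data_dir, "train")
  if (nrow(listing) == 0) stop("empty training split in ", data_dir)
  vlist <- if (val_loss) list_split(data_dir, "val") else NULL
  sz <- model$cfg$input_size
  load_split <- function(lst) {
    lapply(seq_len(nrow(lst)), function(i) {
      img <- read_image(lst$image[i])
      if (dim(img)[1] != sz || dim(img)[2] != sz)
        img <- resize_nearest(img, sz, sz)
      list(x = image_to_tensor(img), boxes = read_labels(lst$label[i]))
    })
  }
  data <- load_split(listing)
  vdata <- if (val_loss && nrow(vlist) > 0) load_split(vlist) else NULL
  if (identical(class_weights, "auto")) {
    freq <- table(factor(unlist(lapply(data, function(d) d$boxes[, 1])),
                         levels = 0:(model$cfg$n_classes - 1)))
    inv <- 1 / pmax(as.numeric(freq), 1)
    class_weights <- inv / mean(inv)
  }
  vel <- lapply(model$nodes, function(nd)
    if (is.null(nd$unit)) NULL else par_zero(nd$unit))
  ema_nodes <- if (ema_decay > 0) lapply(model$nodes, `[[`, "unit")
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        l_box = numeric(0), l_obj = numeric(0),
                        l_cls = numeric(0), val_loss = numeric(0))
  it <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(data))
      ep_loss <- c(loss = 0, l_box = 0, l_obj = 0, l_cls = 0)
      nb <- 0L
      for (start in seq(1, length(ord), by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, length(ord))]
        batch <- data[sel]
        if (augment) batch <- lapply(batch, function(d) {
          if (runif(1) < 0.5) flip_horizontal(d) else d
        })
        xb <- do.call(abind1, lapply(batch, `[[`, "x"))
        labels <- batch_labels(batch)
        it <- it + 1L
        lr_ep <- if (cosine_decay)
          lr * (0.1 + 0.45 * (1 + cos(pi * (ep - 1) / max(epochs - 1, 1))))
        else lr
        lr_t <- if (it <= warmup_iters) lr_ep * it / warmup_iters else lr_ep
        fw <- model_forward(model, xb, training = TRUE)
        model <- fw$model
        ls <- detector_loss(fw$heads, labels, model$cfg,
                            class_weights = class_weights)
        # gradient of loss * batch size (standard scaling for SGD at lr 0.01)
        gh <- lapply(ls$ghead, function(g) g * length(sel))
        gpars <- model_backward(model, xb, fw, gh)
        for (i in seq_along(model$nodes)) {
          if (is.null(gpars[[i]])) next
          r <- sgd_step(model$nodes[[i]]$unit, gpars[[i]], vel[[i]], lr_t,
                        momentum, weight_decay)
          model$nodes[[i]]$unit <- r$unit
          vel[[i]] <- r$vel
        }
        if (ema_decay > 0) {
          # ramp the decay in so early noisy weights wash out quickly
          d_t <- ema_decay * (1 - exp(-it / 100))
          for (i in seq_along(model$nodes))
            if (!is.null(model$nodes[[i]]$unit))
              ema_nodes[[i]] <- ema_update(ema_nodes[[i]],
                                           model$nodes[[i]]$unit, d_t)
        }
        ep_loss <- ep_loss + c(ls$loss, ls$l_box, ls$l_obj, ls$l_cls)
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      vl <- NA_real_
      if (!is.null(vdata)) {
        vx <- do.call(abind1, lapply(vdata, `[[`, "x"))
        vfw <- model_forward(model, vx, training = FALSE)
        vl <- detector_loss(vfw$heads, batch_labels(vdata),
                            model$cfg)$loss
      }
      history[nrow(history) + 1, ] <- list(ep, ep_loss[1], ep_loss[2],
                                           ep_loss[3], ep_loss[4], vl)
      if (verbose)
        message(sprintf("epoch %d  loss %.4f (box %.4f obj %.4f cls %.4f)",
                        ep, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
    }
  })
  raw_model <- NULL
  if (ema_decay > 0) {
    raw_model <- model
    for (i in seq_along(model$nodes))
      if (!is.null(model$nodes[[i]]$unit))
        model$nodes[[i]]$unit <- ema_nodes[[i]]
  }
  structure(list(model = model, raw_model = raw_model, cfg = model$cfg,
                 seed = seed, history = history),
            class = "tflos_fit")
}

#' @export
print.tflos_fit <- function(x, ...) {
  cat("Trained tea-flower detector (", nrow(x$history), " epochs)\n",
      sep = "")
  if (nrow(x$history))
    cat(sprintf("  final loss %.4f\n", tail(x$history$loss, 1)))
  print(x$model)
  invisible(x)
}

# stack (1,C,H,W) tensors along the batch axis
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, c(length(xs), d[2], d[3], d[4]))
  for (i in seq_along(xs)) out[i, , , ] <- xs[[i]][1, , , ]
  out
}

# labels matrix (img, class, cx, cy, w, h) for a loaded batch
batch_labels <- function(batch) {
  rows <- lapply(seq_along(batch), function(i) {
    b <- batch[[i]]$boxes
    if (NROW(b) == 0) return(NULL)
    cbind(i, b[, 1], b[, 2], b[, 3], b[, 4], b[, 5])
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) matrix(numeric(0), 0, 6) else m
}

flip_horizontal <- function(d) {
  x <- d$x
  x <- x[, , , rev(seq_len(dim(x)[4])), drop = FALSE]
  b <- d$boxes
  if (NROW(b) > 0) b[, 2] <- 1 - b[, 2]
  list(x = x, boxes = b)
}

#' Save / load a trained detector checkpoint
#'
#' Checkpoints are self-describing: the config, seed, weights and loss
#' history travel together in one file written with [saveRDS()].
#'
#' @param fit a `tflos_fit`
#' @param path file path
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
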