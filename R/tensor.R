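#' Feature map helpers
#'
#' Feature maps throughout the package are dense 4-d arrays with
#' `dim = c(batch, channel, height, width)`, matching the (N, C, H, W)
#' layout of the field's deep-learning frameworks.
#'
#' @param n,c,h,w dimensions
#' @param sd standard deviation for random fill
#' @return a 4-d array
#' @export
feature_map <- function(n, c, h, w, sd = 0) {
  stopifnot(n >= 1, c >= 1, h >= 1, w >= 1)
  if (sd > 0) array(rnorm(n * c * h * w, sd = sd), c(n, c, h, w))
  else array(0, c(n, c, h, w))
}

check_fmap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4)
    stop("feature map must be a 4-d array (N, C, H, W)")
  if (!all(is.finite(x))) stop("feature map has non-finite entries")
  invisible(x)
}

zeros_like <- function(x) array(0, dim(x))

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- parameter tree utilities -------------------------------------------
# A "unit" is list(cfg = ..., par = list(<numeric arrays>), sub = list(<units>),
# st = list(<non-trainable state>)). Gradients mirror the par/sub structure.

par_zero <- function(unit) {
  out <- list()
  if (!is.null(unit$par)) out$par <- lapply(unit$par, function(a) {
    z <- a; z[] <- 0; z
  })
  if (!is.null(unit$sub)) out$sub <- lapply(unit$sub, par_zero)
  out
}

par_count <- function(unit) {
  n <- 0L
  if (!is.null(unit$par)) n <- n + sum(vapply(unit$par, length, 0L))
  if (!is.null(unit$sub)) n <- n + sum(vapply(unit$sub, par_count, 0L))
  n
}

# in-place-style SGD with (optionally Nesterov) momentum
sgd_step <- function(unit, grad, vel, lr, momentum = 0.937,
                     weight_decay = 0, nesterov = TRUE) {
  if (!is.null(unit$par)) {
    for (nm in names(unit$par)) {
      g <- grad$par[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0 && nm == "w") g <- g + weight_decay * unit$par[[nm]]
      vel$par[[nm]] <- momentum * vel$par[[nm]] - lr * g
      unit$par[[nm]] <- unit$par[[nm]] +
        if (nesterov) momentum * vel$par[[nm]] - lr * g else vel$par[[nm]]
    }
  }
  if (!is.null(unit$sub)) {
    for (i in seq_along(unit$sub)) {
      r <- sgd_step(unit$sub[[i]], grad$sub[[i]], vel$sub[[i]], lr,
                    momentum, weight_decay, nesterov)
      unit$sub[[i]] <- r$unit
      vel$sub[[i]] <- r$vel
    }
  }
  list(unit = unit, vel = vel)
}

# exponential moving average of the trainable leaves of a unit tree;
# non-trainable state (running statistics) is copied from the live unit
ema_update <- function(ema, unit, decay) {
  if (!is.null(unit$par))
    for (nm in names(unit$par))
      ema$par[[nm]] <- decay * ema$par[[nm]] + (1 - decay) * unit$par[[nm]]
  if (!is.null(unit$st)) ema$st <- unit$st
  if (!is.null(unit$sub))
    for (i in seq_along(unit$sub))
      ema$sub[[i]] <- ema_update(ema$sub[[i]], unit$sub[[i]], decay)
  ema
}

grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- list()
  if (!is.null(a$par) || !is.null(b$par)) {
    nms <- union(names(a$par), names(b$par))
    out$par <- setNames(lapply(nms, function(nm) {
      if (is.null(a$par[[nm]])) b$par[[nm]]
      else if (is.null(b$par[[nm]])) a$par[[nm]]
      else a$par[[nm]] + b$par[[nm]]
    }), nms)
  }
  if (!is.null(a$sub) || !is.null(b$sub)) {
    n <- max(length(a$sub), length(b$sub))
    out$sub <- lapply(seq_len(n), function(i) {
      grad_add(if (i <= length(a$sub)) a$sub[[i]] else NULL,
               if (i <= length(b$sub)) b$sub[[i]] else NULL)
    })
  }
  out
}
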