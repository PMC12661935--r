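#' Flowering-stage classification
#'
#' A small feed-forward network that maps per-image flower counts (bud,
#' blooming, withered) plus an encoded observation time to one of the five
#' flowering stages IFS, EFS, MFS, LFS, TFS. The network has an input
#' layer, six hidden ReLU layers and a softmax output (seven layers), and
#' is trained with cross-entropy loss and the Adam optimizer.
#'
#' @name tfsc
NULL

STAGE_LEVELS <- c("IFS", "EFS", "MFS", "LFS", "TFS")

#' Numerically stable softmax
#'
#' Subtracts the maximum before exponentiating (shift invariance), so
#' logits of any magnitude produce probabilities that sum to 1 without
#' overflow.
#'
#' @param o numeric vector of unnormalized scores
#' @return probability vector summing to 1
#' @export
softmax <- function(o) {
  e <- exp(o - max(o))
  e / sum(e)
}

day_of_year_feature <- function(dates) {
  as.integer(strftime(as.Date(dates), "%j")) / 366
}

#' Build train/validation/test stage datasets from count records
#'
#' Applies the documented preprocessing: accessions whose median total
#' count over the season falls below `min_median_total` are removed
#' (insufficient flowers give unreliable stage signals); remaining records
#' of the same accession and date are grouped in threes (input order) and
#' averaged into one sample (remainders of 1-2 records are dropped, keeping
#' the every-three rule exact); the earliest year's samples are split
#' 8:2 into train/validation, later years form the test set. The time
#' feature is day-of-year / 366.
#'
#' @param records data.frame with columns accession, date, bud, b_flower,
#'   w_flower, stage
#' @param min_median_total accession quality threshold
#' @param seed seed for the 8:2 shuffle
#' @return list of data.frames `train`, `val`, `test`, each with columns
#'   bud, b_flower, w_flower, time, stage, accession, date
#' @export
build_stage_dataset <- function(records, min_median_total = 3, seed = 0) {
  stopifnot(all(c("accession", "date", "bud", "b_flower", "w_flower",
                  "stage") %in% names(records)))
  records$date <- as.Date(records$date)
  records$total <- records$bud + records$b_flower + records$w_flower
  med <- tapply(records$total, records$accession, median)
  keep_acc <- names(med)[med >= min_median_total]
  records <- records[records$accession %in% keep_acc, , drop = FALSE]
  if (nrow(records) == 0) stop("no accessions pass the quality filter")
  key <- paste(records$accession, records$date)
  samples <- list()
  for (k in unique(key)) {
    grp <- records[key == k, , drop = FALSE]
    ng <- nrow(grp) %/% 3
    for (j in seq_len(ng)) {
      rows <- grp[(j - 1) * 3 + 1:3, , drop = FALSE]
      st <- unique(rows$stage)
      if (length(st) != 1 || is.na(st) || !nzchar(st))
        stop("group without a unique stage label: ", k)
      samples[[length(samples) + 1]] <- data.frame(
        bud = mean(rows$bud), b_flower = mean(rows$b_flower),
        w_flower = mean(rows$w_flower),
        time = day_of_year_feature(rows$date[1]),
        stage = st, accession = rows$accession[1], date = rows$date[1],
        stringsAsFactors = FALSE)
    }
  }
  s <- do.call(rbind, samples)
  yr <- as.integer(strftime(s$date, "%Y"))
  first <- s[yr == min(yr), , drop = FALSE]
  test <- s[yr > min(yr), , drop = FALSE]
  idx <- with_seed(seed, sample(nrow(first)))
  ntr <- floor(0.8 * nrow(first))
  list(train = first[idx[seq_len(ntr)], , drop = FALSE],
       val = first[idx[-seq_len(ntr)], , drop = FALSE],
       test = test)
}

tfsc_features <- function(samples) {
  as.matrix(samples[, c("bud", "b_flower", "w_flower", "time")])
}

init_tfsc_net <- function(widths = c(64, 64, 32, 32, 16, 16),
                          n_in = 4, n_out = 5) {
  sizes <- c(n_in, widths, n_out)
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1)) {
    W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1],
                           sd = sqrt(2 / sizes[i])), sizes[i], sizes[i + 1])
    b[[i]] <- rep(0, sizes[i + 1])
  }
  list(W = W, b = b)
}

tfsc_fwd <- function(net, X) {
  A <- list(X)
  L <- length(net$W)
  h <- X
  for (i in seq_len(L)) {
    z <- h %*% net$W[[i]] + matrix(net$b[[i]], nrow(h), length(net$b[[i]]),
                                   byrow = TRUE)
    h <- if (i < L) pmax(z, 0) else z
    A[[i + 1]] <- h
  }
  # row-wise stable softmax
  P <- exp(sweep(h, 1, apply(h, 1, max), "-"))
  P <- sweep(P, 1, rowSums(P), "/")
  list(P = P, A = A)
}

#' Train the flowering-stage classifier
#'
#' Standardizes the features with the training split's mean and standard
#' deviation (applied unchanged to validation/test data), then trains the
#' seven-layer network with cross-entropy loss and Adam. Deterministic
#' given the seed. Zero epochs return the freshly initialized net.
#'
#' @param samples training data.frame from [build_stage_dataset()]
#' @param val optional validation data.frame
#' @param epochs,batch_size,lr training parameters (defaults 80 / 16 /
#'   0.001)
#' @param hidden hidden-layer widths (six layers)
#' @param seed RNG seed
#' @return a `tfsc_model` with weights, the feature scaler, stage levels
#'   and a per-epoch history of loss and accuracy
#' @export
train_tfsc <- function(samples, val = NULL, epochs = 80, batch_size = 16,
                       lr = 0.001, hidden = c(64, 64, 32, 32, 16, 16),
                       seed = 0) {
  X <- tfsc_features(samples)
  yl <- factor(samples$stage, levels = STAGE_LEVELS)
  if (any(is.na(yl))) stop("unknown stage labels present")
  if (length(unique(yl)) < 2)
    stop("training data contain a single stage class; refusing to train")
  y <- as.integer(yl)
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")
  Xv <- NULL; yv <- NULL
  if (!is.null(val) && nrow(val) > 0) {
    Xv <- sweep(sweep(tfsc_features(val), 2, mu, "-"), 2, sg, "/")
    yv <- as.integer(factor(val$stage, levels = STAGE_LEVELS))
  }
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  net <- with_seed(seed, init_tfsc_net(hidden))
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(bb) bb * 0); vb <- mb
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(Xs))
      tot <- 0; nb <- 0
      for (st in seq(1, length(ord), by = batch_size)) {
        sel <- ord[st:min(st + batch_size - 1, length(ord))]
        Xb <- Xs[sel, , drop = FALSE]
        yb <- y[sel]
        fw <- tfsc_fwd(net, Xb)
        n <- length(sel)
        Yb <- matrix(0, n, 5); Yb[cbind(seq_len(n), yb)] <- 1
        tot <- tot + -mean(log(pmax(fw$P[cbind(seq_len(n), yb)], 1e-12)))
        nb <- nb + 1
        delta <- (fw$P - Yb) / n
        t_step <- t_step + 1
        for (i in rev(seq_len(L))) {
          gW <- t(fw$A[[i]]) %*% delta
          gb <- colSums(delta)
          if (i > 1) delta <- (delta %*% t(net$W[[i]])) * (fw$A[[i]] > 0)
          mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW
          vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW^2
          mb[[i]] <- b1 * mb[[i]] + (1 - b1) * gb
          vb[[i]] <- b2 * vb[[i]] + (1 - b2) * gb^2
          corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
          net$W[[i]] <- net$W[[i]] - lr * corr * mW[[i]] /
            (sqrt(vW[[i]]) + eps)
          net$b[[i]] <- net$b[[i]] - lr * corr * mb[[i]] /
            (sqrt(vb[[i]]) + eps)
        }
      }
      fw_all <- tfsc_fwd(net, Xs)
      acc <- mean(max.col(fw_all$P, ties.method = "first") == y)
      vl <- NA_real_; va <- NA_real_
      if (!is.null(Xv)) {
        fv <- tfsc_fwd(net, Xv)
        vl <- -mean(log(pmax(fv$P[cbind(seq_along(yv), yv)], 1e-12)))
        va <- mean(max.col(fv$P, ties.method = "first") == yv)
      }
      hist[nrow(hist) + 1, ] <- list(ep, tot / max(nb, 1), acc, vl, va)
    }
  })
  structure(list(net = net, scaler = list(mean = mu, sd = sg),
                 levels = STAGE_LEVELS, history = hist, seed = seed),
            class = "tfsc_model")
}

#' @export
print.tfsc_model <- function(x, ...) {
  cat("Flowering-stage classifier (7-layer network)\n")
  if (nrow(x$history))
    cat(sprintf("  %d epochs, final training accuracy %.3f\n",
                nrow(x$history), tail(x$history$acc, 1)))
  invisible(x)
}

#' Predict flowering stages
#'
#' Returns the argmax stage (ties broken by the lowest stage index) and the
#' five class probabilities per sample; batch order is preserved.
#'
#' @param net a `tfsc_model`
#' @param samples data.frame with columns bud, b_flower, w_flower, time
#' @return data.frame with `stage` and probability columns p_IFS..p_TFS
#' @export
predict_stage <- function(net, samples) {
  X <- tfsc_features(samples)
  Xs <- sweep(sweep(X, 2, net$scaler$mean, "-"), 2, net$scaler$sd, "/")
  P <- tfsc_fwd(net$net, Xs)$P
  idx <- max.col(P, ties.method = "first")
  out <- data.frame(stage = net$levels[idx], stringsAsFactors = FALSE)
  colnames(P) <- paste0("p_", net$levels)
  cbind(out, as.data.frame(P))
}

#' @export
predict.tfsc_model <- function(object, newdata, ...) {
  predict_stage(object, newdata)
}

#' Evaluate stage predictions
#'
#' Accuracy (trace over total), the 5 x 5 confusion matrix (rows = true
#' stage, columns = predicted) and the adjacent-stage error rate: the share
#' of off-diagonal mass on the first off-diagonals, since confusion between
#' neighbouring stages is the expected failure mode.
#'
#' @param predictions character vector of predicted stages
#' @param labels character vector of true stages
#' @return list(accuracy, confusion, adjacent_error_rate)
#' @export
evaluate_stages <- function(predictions, labels) {
  p <- factor(predictions, levels = STAGE_LEVELS)
  y <- factor(labels, levels = STAGE_LEVELS)
  cm <- table(truth = y, predicted = p)
  off <- sum(cm) - sum(diag(cm))
  adj <- sum(cm[cbind(1:4, 2:5)]) + sum(cm[cbind(2:5, 1:4)])
  list(accuracy = sum(diag(cm)) / sum(cm),
       confusion = cm,
       adjacent_error_rate = if (off > 0) adj / off else NA_real_)
}

#' Classify a count series, averaging same-date replicates
#'
#' At inference, records sharing accession and date are averaged in groups
#' of three when at least three exist (mirroring the training-data rule);
#' otherwise raw records are used and flagged in the `averaged` column.
#'
#' @param net a `tfsc_model`
#' @param counts data.frame with accession, date, bud, b_flower, w_flower
#' @return per-sample predictions with accession, date, averaged flag,
#'   stage and probabilities
#' @export
classify_stage_series <- function(net, counts) {
  counts$date <- as.Date(counts$date)
  key <- paste(counts$accession, counts$date)
  out <- list()
  for (k in unique(key)) {
    grp <- counts[key == k, , drop = FALSE]
    if (nrow(grp) >= 3) {
      ng <- nrow(grp) %/% 3
      feat <- do.call(rbind, lapply(seq_len(ng), function(j) {
        rows <- grp[(j - 1) * 3 + 1:3, , drop = FALSE]
        data.frame(bud = mean(rows$bud), b_flower = mean(rows$b_flower),
                   w_flower = mean(rows$w_flower),
                   time = day_of_year_feature(rows$date[1]))
      }))
      avg <- TRUE
    } else {
      feat <- data.frame(bud = grp$bud, b_flower = grp$b_flower,
                         w_flower = grp$w_flower,
                         time = day_of_year_feature(grp$date))
      avg <- FALSE
    }
    pr <- predict_stage(net, feat)
    out[[length(out) + 1]] <- cbind(
      data.frame(accession = grp$accession[1], date = grp$date[1],
                 averaged = avg, stringsAsFactors = FALSE), pr)
  }
  do.call(rbind, out)
}
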