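# Residual 1-D CNN classifying fixed-length 6-channel IMU windows into
# {idle, walk, stairs, run, fall}. Stem convolution, two residual blocks
# (identity and 1x1-projection shortcuts), global average pooling and a
# dense softmax head. Inputs are standardized per channel with training-set
# statistics. Trained with the same loss/optimizer/schedule as the
# segmentation network.

#' Configuration for the activity classifier
#'
#' @param window_s Window length in seconds.
#' @param fs IMU sampling rate, Hz.
#' @param classes Activity classes (output order).
#' @param stem_filters,block_filters Channel widths of the stem and of the
#'   two residual blocks.
#' @param lr0,lr_drop_factor,patience,epochs,batch_size,val_frac,k_folds,seed
#'   Training schedule, as in [seq2seq_config()].
#' @return A list of class `activity_config`.
#' @export
activity_config <- function(window_s = 4, fs = 50,
                            classes = c("idle", "walk", "stairs", "run",
                                        "fall"),
                            stem_filters = 16, block_filters = c(16, 32),
                            lr0 = 0.001, lr_drop_factor = 10, patience = 2,
                            epochs = 12, batch_size = 32, val_frac = 0.2,
                            k_folds = 4, seed = 1L) {
  L <- window_s * fs
  if (L %% 8 != 0) stop("window_s * fs must be divisible by 8")
  n_classes <- length(classes)
  n_channels <- 6L
  structure(as.list(environment()), class = "activity_config")
}

#' Build an untrained activity classifier
#'
#' @param cfg An [activity_config()].
#' @return An object of class `activity_resnet` mapping a
#'   `(window_s * fs, 6)` window to a probability vector over the classes.
#' @export
build_activity_model <- function(cfg) {
  stopifnot(inherits(cfg, "activity_config"))
  set.seed(cfg$seed)
  C0 <- cfg$stem_filters; C1 <- cfg$block_filters[1]; C2 <- cfg$block_filters[2]
  if (C1 != C0) stop("first block width must equal stem width")
  K <- cfg$n_classes
  p <- list()
  p$c0_W <- nn_init_conv(7, cfg$n_channels, C0); p$c0_b <- numeric(C0)
  p$c0_g <- rep(1, C0); p$c0_be <- numeric(C0)
  p$r1a_W <- nn_init_conv(5, C0, C1); p$r1a_b <- numeric(C1)
  p$r1a_g <- rep(1, C1); p$r1a_be <- numeric(C1)
  p$r1b_W <- nn_init_conv(5, C1, C1); p$r1b_b <- numeric(C1)
  p$r1b_g <- rep(1, C1); p$r1b_be <- numeric(C1)
  p$r2a_W <- nn_init_conv(5, C1, C2); p$r2a_b <- numeric(C2)
  p$r2a_g <- rep(1, C2); p$r2a_be <- numeric(C2)
  p$r2b_W <- nn_init_conv(5, C2, C2); p$r2b_b <- numeric(C2)
  p$r2b_g <- rep(1, C2); p$r2b_be <- numeric(C2)
  p$r2s_W <- nn_init_conv(1, C1, C2); p$r2s_b <- numeric(C2)
  p$fc_W <- matrix(stats::runif(C2 * K, -sqrt(6 / C2), sqrt(6 / C2)), C2, K)
  p$fc_b <- numeric(K)
  structure(list(params = p, run_stats = list(), cfg = cfg,
                 class_names = cfg$classes, norm = NULL, history = NULL),
            class = "activity_resnet")
}

#' @export
print.activity_resnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<activity_resnet> (%d, %d) -> %d classes, %d parameters%s\n",
              x$cfg$L, x$cfg$n_channels, x$cfg$n_classes, np,
              if (is.null(x$norm)) " (untrained)" else ""))
  invisible(x)
}

act_forward <- function(p, x, cfg, training = FALSE, run_stats = list()) {
  cache <- list(); bn_batch <- list()
  bn <- function(h, name) {
    r <- nn_bn_fwd(h, p[[paste0(name, "_g")]], p[[paste0(name, "_be")]],
                   training = training, run_stats = run_stats[[name]])
    cache[[paste0(name, "_bn")]] <<- r$cache
    if (training) bn_batch[[name]] <<- list(mu = r$mu, var = r$var)
    r$out
  }
  relu <- function(h, name) {
    a <- nn_act_fwd(h, "relu")
    cache[[paste0(name, "_act")]] <<- a$mask
    a$out
  }
  cache$c0_in <- x
  h <- nn_conv_fwd(x, p$c0_W, p$c0_b, 2L)
  h <- bn(h, "c0"); h <- relu(h, "c0")
  # residual block 1 (identity shortcut)
  cache$r1_in <- h
  z <- nn_conv_fwd(h, p$r1a_W, p$r1a_b, 1L)
  z <- bn(z, "r1a"); z <- relu(z, "r1a")
  cache$r1b_in <- z
  z <- nn_conv_fwd(z, p$r1b_W, p$r1b_b, 1L)
  z <- bn(z, "r1b")
  h <- relu(z + h, "r1o")
  pl <- nn_pool_fwd(h); cache$p1_arg <- pl$arg; h <- pl$out
  # residual block 2 (1x1 projection shortcut)
  cache$r2_in <- h
  z <- nn_conv_fwd(h, p$r2a_W, p$r2a_b, 1L)
  z <- bn(z, "r2a"); z <- relu(z, "r2a")
  cache$r2b_in <- z
  z <- nn_conv_fwd(z, p$r2b_W, p$r2b_b, 1L)
  z <- bn(z, "r2b")
  sc <- nn_conv_fwd(h, p$r2s_W, p$r2s_b, 1L)
  h <- relu(z + sc, "r2o")
  pl <- nn_pool_fwd(h); cache$p2_arg <- pl$arg; h <- pl$out
  cache$gap_in_len <- dim(h)[1]
  g <- apply(h, c(2, 3), mean)                      # (C2, N)
  if (is.null(dim(g))) g <- matrix(g, ncol = dim(h)[3])
  cache$gap_out <- g
  logits <- t(p$fc_W) %*% g + p$fc_b                # (K, N)
  list(logits = logits, cache = cache, bn_batch = bn_batch)
}

act_backward <- function(p, cache, dlogits, cfg) {
  g <- list()
  bn_bwd <- function(dy, name) {
    r <- nn_bn_bwd(dy, cache[[paste0(name, "_bn")]])
    g[[paste0(name, "_g")]] <<- r$dgamma
    g[[paste0(name, "_be")]] <<- r$dbeta
    r$dx
  }
  relu_bwd <- function(dy, name) dy * cache[[paste0(name, "_act")]]

  g$fc_W <- cache$gap_out %*% t(dlogits)
  g$fc_b <- rowSums(dlogits)
  dg <- p$fc_W %*% dlogits                          # (C2, N)
  Lg <- cache$gap_in_len
  dh <- array(0, c(Lg, nrow(dg), ncol(dg)))
  for (n in seq_len(ncol(dg)))
    dh[, , n] <- matrix(dg[, n] / Lg, Lg, nrow(dg), byrow = TRUE)
  dh <- nn_pool_bwd(cache$p2_arg, dh)
  dh <- relu_bwd(dh, "r2o")
  sb <- nn_conv_bwd(cache$r2_in, p$r2s_W, dh, 1L)
  g$r2s_W <- sb$dW; g$r2s_b <- sb$db
  dz <- bn_bwd(dh, "r2b")
  cb <- nn_conv_bwd(cache$r2b_in, p$r2b_W, dz, 1L)
  g$r2b_W <- cb$dW; g$r2b_b <- cb$db
  dz <- relu_bwd(cb$dx, "r2a")
  dz <- bn_bwd(dz, "r2a")
  cb <- nn_conv_bwd(cache$r2_in, p$r2a_W, dz, 1L)
  g$r2a_W <- cb$dW; g$r2a_b <- cb$db
  dh <- sb$dx + cb$dx
  dh <- nn_pool_bwd(cache$p1_arg, dh)
  dh <- relu_bwd(dh, "r1o")
  dz <- bn_bwd(dh, "r1b")
  cb <- nn_conv_bwd(cache$r1b_in, p$r1b_W, dz, 1L)
  g$r1b_W <- cb$dW; g$r1b_b <- cb$db
  dz <- relu_bwd(cb$dx, "r1a")
  dz <- bn_bwd(dz, "r1a")
  cb <- nn_conv_bwd(cache$r1_in, p$r1a_W, dz, 1L)
  g$r1a_W <- cb$dW; g$r1a_b <- cb$db
  dh <- dh + cb$dx                                  # identity shortcut
  dh <- relu_bwd(dh, "c0")
  dh <- bn_bwd(dh, "c0")
  cb <- nn_conv_bwd(cache$c0_in, p$c0_W, dh, 2L)
  g$c0_W <- cb$dW; g$c0_b <- cb$db
  g
}

act_standardize <- function(x, norm) {
  # x: (n, L, 6) array
  for (c in 1:6) x[, , c] <- (x[, , c] - norm$mu[c]) / norm$sd[c]
  x
}

#' Class probabilities for IMU windows
#'
#' @param model A trained `activity_resnet`.
#' @param x Array (n, L, 6) of raw IMU windows (acc then gyro channels).
#' @param batch_size Scoring batch size.
#' @return Matrix (n, n_classes) of probabilities, rows summing to 1.
#' @export
predict_activity <- function(model, x, batch_size = 128) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  if (!is.null(model$norm)) x <- act_standardize(x, model$norm)
  n <- dim(x)[1]
  out <- matrix(0, n, model$cfg$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1)
    xb <- aperm(x[idx, , , drop = FALSE], c(2, 3, 1))
    fw <- act_forward(model$params, xb, model$cfg, training = FALSE,
                      run_stats = model$run_stats)
    z <- t(fw$logits)
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    out[idx, ] <- ez / rowSums(ez)
  }
  colnames(out) <- model$class_names
  out
}

#' Train the activity classifier
#'
#' Same protocol as [train_seq2seq()]: categorical cross-entropy, Adam from
#' `lr0`, reduce-on-plateau schedule, 80/20 train/validation split.
#' Per-channel standardization statistics are computed on the training split
#' and stored in the model.
#'
#' @param ds Dataset from [make_imu_training_set()].
#' @param cfg An [activity_config()].
#' @param train_idx Window indices to train on (default: all).
#' @param verbose Print progress.
#' @return A trained `activity_resnet` with `history`.
#' @export
train_activity <- function(ds, cfg, train_idx = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "activity_config"))
  if (is.null(train_idx)) train_idx <- seq_len(dim(ds$x)[1])
  model <- build_activity_model(cfg)
  y_all <- as.integer(factor(ds$label, levels = cfg$classes)) - 1L
  if (anyNA(y_all[train_idx])) stop("labels outside cfg$classes")
  set.seed(cfg$seed + 1L)
  perm <- sample(train_idx)
  n_val <- max(1L, round(cfg$val_frac * length(train_idx)))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  model$norm <- list(
    mu = vapply(1:6, function(c) mean(ds$x[tr_idx, , c]), 0),
    sd = vapply(1:6, function(c) max(stats::sd(ds$x[tr_idx, , c]), 1e-6), 0))
  xs <- act_standardize(ds$x, model$norm)
  adam <- nn_adam_init(model$params)
  lr <- cfg$lr0
  best_val <- -Inf; stall <- 0L; hist <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; tn <- 0; tacc <- 0
    for (s in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[s:min(length(ord), s + cfg$batch_size - 1)]
      xb <- aperm(xs[bidx, , , drop = FALSE], c(2, 3, 1))
      yb <- y_all[bidx]
      fw <- act_forward(model$params, xb, cfg, training = TRUE,
                        run_stats = model$run_stats)
      for (nm in names(fw$bn_batch))
        model$run_stats <- nn_update_run_stats(model$run_stats, nm,
                                               fw$bn_batch[[nm]]$mu,
                                               fw$bn_batch[[nm]]$var)
      sm <- class_softmax_ce(fw$logits, yb)
      grads <- act_backward(model$params, fw$cache, sm$dlogits, cfg)
      st <- nn_adam_step(model$params, grads, adam, lr)
      model$params <- st$params; adam <- st$state
      tacc <- tacc + sum(max.col(t(sm$probs)) - 1L == yb)
      tl <- tl + sm$loss * length(yb); tn <- tn + length(yb)
    }
    pv <- predict_activity_std(model, xs[val_idx, , , drop = FALSE])
    vacc <- mean(max.col(pv) - 1L == y_all[val_idx])
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, train_loss = tl / tn,
                                   train_acc = tacc / tn, val_acc = vacc))
    if (verbose)
      message(sprintf("epoch %2d lr %.4g loss %.4f acc %.3f val %.3f",
                      ep, lr, tl / tn, tacc / tn, vacc))
    if (vacc > best_val + 1e-4) { best_val <- vacc; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= cfg$patience) { lr <- lr / cfg$lr_drop_factor; stall <- 0L }
    }
  }
  model$history <- hist
  model
}

# predict on already-standardized windows
predict_activity_std <- function(model, xs, batch_size = 128) {
  n <- dim(xs)[1]
  out <- matrix(0, n, model$cfg$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1)
    xb <- aperm(xs[idx, , , drop = FALSE], c(2, 3, 1))
    fw <- act_forward(model$params, xb, model$cfg, training = FALSE,
                      run_stats = model$run_stats)
    z <- t(fw$logits); z <- z - apply(z, 1, max)
    ez <- exp(z)
    out[idx, ] <- ez / rowSums(ez)
  }
  out
}

# softmax cross-entropy for (K, N) logits and integer labels 0..K-1
class_softmax_ce <- function(logits, y) {
  z <- t(logits)
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  pr <- ez / rowSums(ez)
  yi <- y + 1L
  n <- length(yi)
  loss <- -mean(log(pr[cbind(seq_len(n), yi)] + 1e-12))
  dz <- pr
  dz[cbind(seq_len(n), yi)] <- dz[cbind(seq_len(n), yi)] - 1
  list(loss = loss, probs = t(pr), dlogits = t(dz) / n)
}

#' Cross-validated evaluation of the activity classifier
#'
#' Disjoint folds stratified by activity label; per-window accuracy.
#'
#' @param ds Dataset from [make_imu_training_set()].
#' @param cfg An [activity_config()].
#' @param verbose Print per-fold progress.
#' @return List: `fold_acc`, `acc_mean`, `acc_sd`, `confusion`.
#' @export
evaluate_activity_cv <- function(ds, cfg, verbose = FALSE) {
  n <- dim(ds$x)[1]
  K <- cfg$n_classes
  if (n < cfg$k_folds * K) stop("dataset too small for ", cfg$k_folds, " folds")
  set.seed(cfg$seed + 2L)
  fold <- integer(n)
  for (g in unique(as.character(ds$label))) {
    idx <- sample(which(as.character(ds$label) == g))
    fold[idx] <- rep_len(seq_len(cfg$k_folds), length(idx))
  }
  y_all <- as.integer(factor(ds$label, levels = cfg$classes)) - 1L
  conf <- matrix(0L, K, K, dimnames = list(true = cfg$classes,
                                           pred = cfg$classes))
  fold_acc <- numeric(cfg$k_folds)
  for (kf in seq_len(cfg$k_folds)) {
    te <- which(fold == kf); tr <- which(fold != kf)
    m <- train_activity(ds, cfg, train_idx = tr)
    pr <- predict_activity(m, ds$x[te, , , drop = FALSE])
    pred <- max.col(pr) - 1L
    fold_acc[kf] <- mean(pred == y_all[te])
    conf <- conf + as.matrix(table(factor(y_all[te], levels = 0:(K - 1)),
                                   factor(pred, levels = 0:(K - 1))))
    if (verbose) message(sprintf("fold %d accuracy %.4f", kf, fold_acc[kf]))
  }
  list(fold_acc = fold_acc, acc_mean = mean(fold_acc),
       acc_sd = stats::sd(fold_acc), confusion = conf)
}

#' Classify a continuous IMU stream
#'
#' Slides half-overlapping windows over the stream and classifies each.
#' Windows predicted as falls are additionally gated by a transient-magnitude
#' pre-check: without an acceleration transient above `gate_g` the prediction
#' is demoted to the runner-up class. The gate threshold sits well below the
#' 3 g transient a genuine fall produces, so real falls are never suppressed.
#'
#' @param model A trained `activity_resnet`.
#' @param imu An [imu_record()] at the model's sampling rate.
#' @param gate_g Fall-gate acceleration threshold in g.
#' @return Data.frame: `t` (window center, s), `class`, `confidence`.
#' @export
classify_stream <- function(model, imu, gate_g = 2) {
  stopifnot(inherits(model, "activity_resnet"), inherits(imu, "imu_record"))
  if (abs(imu$fs - model$cfg$fs) > 1e-9)
    stop("stream rate ", imu$fs, " does not match model rate ", model$cfg$fs)
  L <- model$cfg$L
  n <- nrow(imu$acc)
  if (n < L) stop("stream shorter than one window")
  step <- L %/% 2L
  starts <- seq(1L, n - L + 1L, by = step)
  x <- array(0, c(length(starts), L, 6))
  for (i in seq_along(starts))
    x[i, , ] <- cbind(imu$acc, imu$gyro)[starts[i]:(starts[i] + L - 1L), ]
  pr <- predict_activity(model, x)
  pred <- max.col(pr)
  amag <- sqrt(rowSums(imu$acc^2))
  fall_i <- which(model$class_names == "fall")
  for (i in seq_along(starts)) {
    if (length(fall_i) && pred[i] == fall_i) {
      seg <- amag[starts[i]:(starts[i] + L - 1L)]
      if (max(seg) < gate_g * G_MSS) {
        ord <- order(pr[i, ], decreasing = TRUE)
        pred[i] <- ord[2]
      }
    }
  }
  data.frame(t = (starts - 1L + L / 2) / imu$fs,
             class = model$class_names[pred],
             confidence = pr[cbind(seq_along(pred), pred)])
}
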