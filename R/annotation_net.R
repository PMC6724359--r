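# Sequence-to-sequence ECG annotation network: an encoder-decoder 1-D CNN
# mapping an (L, 1) window to an (L, K) per-sample class probability field.
# Encoder: two strided stem convolutions and a max-pool (L -> L/8), then a
# stack of Inception-style blocks (parallel kernel-1/3/5 branches, filter
# concatenation, batch norm). Decoder: three stages of x2 up-sampling plus
# convolution, with skip concatenations from the encoder layer of matching
# length. A kernel-1 head and per-sample softmax produce the class scores.

#' Configuration for the ECG segmentation network
#'
#' @param seq_len Window length in samples (must be divisible by 8;
#'   2000 = 8 s at 250 Hz).
#' @param n_classes Number of per-sample output classes.
#' @param stem_filters,stem_kernel Stem convolution width and kernel size
#'   (two stride-2 convolutions).
#' @param n_blocks Number of Inception-style encoder blocks.
#' @param branch_filters Filters per branch inside each block (the block
#'   emits `3 * branch_filters` channels).
#' @param decoder_filters Filters per decoder stage.
#' @param activation `"linear"` (batch norm with identity activation inside
#'   blocks; nonlinearity enters through max-pooling) or `"relu"`.
#' @param lr0 Starting Adam learning rate.
#' @param lr_drop_factor Factor the learning rate is divided by on a
#'   validation-accuracy plateau.
#' @param patience Consecutive non-improving validation epochs before the
#'   learning-rate drop.
#' @param epochs,batch_size Training schedule.
#' @param val_frac Fraction of the training split held out for validation
#'   (80/20 within the training set).
#' @param k_folds Folds for cross-validated evaluation.
#' @param class_weighting Use inverse-frequency class weights in the loss.
#' @param seed Seed for initialization and shuffling.
#' @return A list of class `seq2seq_config`.
#' @export
seq2seq_config <- function(seq_len = 2000, n_classes = 9,
                           stem_filters = 32, stem_kernel = 7,
                           n_blocks = 4, branch_filters = 32,
                           decoder_filters = 32, activation = "linear",
                           deep_pool = (seq_len %% 16 == 0),
                           lr0 = 0.001, lr_drop_factor = 10, patience = 2,
                           epochs = 20, batch_size = 16, val_frac = 0.2,
                           k_folds = 4, class_weighting = TRUE, seed = 1L) {
  if (seq_len %% 8 != 0) stop("seq_len must be divisible by 8")
  if (deep_pool && seq_len %% 16 != 0)
    stop("deep_pool requires seq_len divisible by 16")
  if (deep_pool && n_blocks < 2) stop("deep_pool requires >= 2 blocks")
  if (!activation %in% c("linear", "relu")) stop("unknown activation")
  structure(as.list(environment()), class = "seq2seq_config")
}

#' Desk-scale segmentation network configuration
#'
#' A reduced-width variant (12-filter stem, two blocks of 8-filter branches,
#' 16-filter decoder, relu activations, unweighted loss, Adam at 3e-3) sized
#' so that a four-fold cross-validation on a few thousand synthetic windows
#' runs in minutes on one CPU core.
#'
#' @param n_classes Number of output classes.
#' @param epochs Training epochs per fold.
#' @param seed Seed.
#' @return A `seq2seq_config`.
#' @export
seq2seq_scaled_config <- function(n_classes = 4, epochs = 6, seed = 1L) {
  seq2seq_config(n_classes = n_classes, stem_filters = 12, n_blocks = 2,
                 branch_filters = 8, decoder_filters = 16,
                 activation = "relu", epochs = epochs, batch_size = 32,
                 lr0 = 0.003, class_weighting = FALSE, seed = seed)
}

#' Build an untrained segmentation model
#'
#' @param cfg A [seq2seq_config()].
#' @param class_names Optional class names (length `n_classes`).
#' @return An object of class `ecg_seq2seq` with initialized parameters.
#' @export
build_seq2seq <- function(cfg, class_names = NULL) {
  stopifnot(inherits(cfg, "seq2seq_config"))
  set.seed(cfg$seed)
  F0 <- cfg$stem_filters; f <- cfg$branch_filters
  Fd <- cfg$decoder_filters; K <- cfg$n_classes; ks <- cfg$stem_kernel
  p <- list()
  p$s1_W <- nn_init_conv(ks, 1, F0); p$s1_b <- numeric(F0)
  p$s1_g <- rep(1, F0); p$s1_be <- numeric(F0)
  p$s2_W <- nn_init_conv(ks, F0, F0); p$s2_b <- numeric(F0)
  p$s2_g <- rep(1, F0); p$s2_be <- numeric(F0)
  cin <- F0
  for (i in seq_len(cfg$n_blocks)) {
    for (k in c(1, 3, 5)) {
      p[[sprintf("b%d_W%d", i, k)]] <- nn_init_conv(k, cin, f)
      p[[sprintf("b%d_b%d", i, k)]] <- numeric(f)
    }
    p[[sprintf("b%d_g", i)]] <- rep(1, 3 * f)
    p[[sprintf("b%d_be", i)]] <- numeric(3 * f)
    cin <- 3 * f
  }
  dec_in <- if (cfg$deep_pool) c(3 * f, Fd + 3 * f, Fd + F0, Fd + F0)
            else c(3 * f, Fd + F0, Fd + F0)
  for (j in seq_along(dec_in)) {
    p[[sprintf("d%d_W", j)]] <- nn_init_conv(5, dec_in[j], Fd)
    p[[sprintf("d%d_b", j)]] <- numeric(Fd)
    p[[sprintf("d%d_g", j)]] <- rep(1, Fd)
    p[[sprintf("d%d_be", j)]] <- numeric(Fd)
  }
  p$h_W <- nn_init_conv(1, Fd, K); p$h_b <- numeric(K)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K) - 1)
  structure(list(params = p, run_stats = list(), cfg = cfg,
                 class_names = class_names, history = NULL),
            class = "ecg_seq2seq")
}

#' @export
print.ecg_seq2seq <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<ecg_seq2seq> (%d, 1) -> (%d, %d), %d blocks, %d parameters%s\n",
              x$cfg$seq_len, x$cfg$seq_len, x$cfg$n_classes, x$cfg$n_blocks,
              np, if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# forward pass; x: (L, 1, N). Returns logits, layer caches and (in training)
# batch statistics for the running-stats update.
seg_forward <- function(p, x, cfg, training = FALSE, run_stats = list()) {
  act <- cfg$activation
  cache <- list(); bn_batch <- list()
  bn <- function(h, name) {
    r <- nn_bn_fwd(h, p[[paste0(name, "_g")]], p[[paste0(name, "_be")]],
                   training = training, run_stats = run_stats[[name]])
    cache[[paste0(name, "_bn")]] <<- r$cache
    if (training) bn_batch[[name]] <<- list(mu = r$mu, var = r$var)
    r$out
  }
  actf <- function(h, name) {
    a <- nn_act_fwd(h, act)
    cache[[paste0(name, "_act")]] <<- a$mask
    a$out
  }
  cache$x <- x
  h <- nn_conv_fwd(x, p$s1_W, p$s1_b, 2L); cache$s1_in <- x
  h <- bn(h, "s1"); s0 <- h <- actf(h, "s1")                     # L/2
  cache$s2_in <- h
  h <- nn_conv_fwd(h, p$s2_W, p$s2_b, 2L)
  h <- bn(h, "s2"); s1 <- h <- actf(h, "s2")                     # L/4
  pl <- nn_pool_fwd(h); cache$pool_arg <- pl$arg; h <- pl$out    # L/8
  sC <- NULL
  for (i in seq_len(cfg$n_blocks)) {
    cache[[sprintf("b%d_in", i)]] <- h
    br <- lapply(c(1, 3, 5), function(k)
      nn_conv_fwd(h, p[[sprintf("b%d_W%d", i, k)]],
                  p[[sprintf("b%d_b%d", i, k)]], 1L))
    h <- nn_concat_fwd(nn_concat_fwd(br[[1]], br[[2]]), br[[3]])
    h <- bn(h, sprintf("b%d", i))
    h <- actf(h, sprintf("b%d", i))
    if (cfg$deep_pool && i == 1L) {                              # L/16
      sC <- h
      pl <- nn_pool_fwd(h); cache$pool2_arg <- pl$arg; h <- pl$out
    }
  }
  # decoder: one up-sample stage per encoder halving; skip concatenations at
  # the matching lengths (deepest first)
  skips <- if (cfg$deep_pool) list(sC, s1, s0) else list(s1, s0)
  n_dec <- length(skips) + 1L
  for (j in seq_len(n_dec)) {
    h <- nn_upsample2_fwd(h)
    cache[[sprintf("d%d_in", j)]] <- h
    h <- nn_conv_fwd(h, p[[sprintf("d%d_W", j)]], p[[sprintf("d%d_b", j)]], 1L)
    h <- bn(h, sprintf("d%d", j))
    h <- actf(h, sprintf("d%d", j))
    if (j < n_dec) {
      cache[[sprintf("d%d_cw", j)]] <- dim(h)[2]
      h <- nn_concat_fwd(h, skips[[j]])
    }
  }
  cache$h_in <- h
  logits <- nn_conv_fwd(h, p$h_W, p$h_b, 1L)
  list(logits = logits, cache = cache, bn_batch = bn_batch)
}

seg_backward <- function(p, cache, dlogits, cfg) {
  act <- cfg$activation
  g <- list()
  bn_bwd <- function(dy, name) {
    r <- nn_bn_bwd(dy, cache[[paste0(name, "_bn")]])
    g[[paste0(name, "_g")]] <<- r$dgamma
    g[[paste0(name, "_be")]] <<- r$dbeta
    r$dx
  }
  act_bwd <- function(dy, name)
    nn_act_bwd(dy, list(mask = cache[[paste0(name, "_act")]]), act)

  hb <- nn_conv_bwd(cache$h_in, p$h_W, dlogits, 1L)
  g$h_W <- hb$dW; g$h_b <- hb$db
  dh <- hb$dx
  n_skip <- if (cfg$deep_pool) 3L else 2L
  n_dec <- n_skip + 1L
  dskip <- vector("list", n_skip)
  for (j in n_dec:1) {
    if (j < n_dec) {
      sp <- nn_concat_bwd(dh, cache[[sprintf("d%d_cw", j)]])
      dh <- sp$da; dskip[[j]] <- sp$db
    }
    dh <- act_bwd(dh, sprintf("d%d", j))
    dh <- bn_bwd(dh, sprintf("d%d", j))
    cb <- nn_conv_bwd(cache[[sprintf("d%d_in", j)]],
                      p[[sprintf("d%d_W", j)]], dh, 1L)
    g[[sprintf("d%d_W", j)]] <- cb$dW; g[[sprintf("d%d_b", j)]] <- cb$db
    dh <- nn_upsample2_bwd(cb$dx)
  }
  for (i in cfg$n_blocks:1) {
    if (cfg$deep_pool && i == 1L) {
      # undo the extra pool and fold in the gradient of the deep skip
      dh <- nn_pool_bwd(cache$pool2_arg, dh)
      dh <- dh + dskip[[1]]
    }
    dh <- act_bwd(dh, sprintf("b%d", i))
    dh <- bn_bwd(dh, sprintf("b%d", i))
    f <- cfg$branch_filters
    xin <- cache[[sprintf("b%d_in", i)]]
    dxin <- xin * 0
    off <- 0
    for (k in c(1, 3, 5)) {
      dbr <- dh[, off + seq_len(f), , drop = FALSE]
      cb <- nn_conv_bwd(xin, p[[sprintf("b%d_W%d", i, k)]], dbr, 1L)
      g[[sprintf("b%d_W%d", i, k)]] <- cb$dW
      g[[sprintf("b%d_b%d", i, k)]] <- cb$db
      dxin <- dxin + cb$dx
      off <- off + f
    }
    dh <- dxin
  }
  dh <- nn_pool_bwd(cache$pool_arg, dh)
  dh <- dh + dskip[[if (cfg$deep_pool) 2L else 1L]]   # skip from stem conv 2
  dh <- act_bwd(dh, "s2")
  dh <- bn_bwd(dh, "s2")
  cb <- nn_conv_bwd(cache$s2_in, p$s2_W, dh, 2L)
  g$s2_W <- cb$dW; g$s2_b <- cb$db
  dh <- cb$dx + dskip[[if (cfg$deep_pool) 3L else 2L]]  # skip from stem conv 1
  dh <- act_bwd(dh, "s1")
  dh <- bn_bwd(dh, "s1")
  cb <- nn_conv_bwd(cache$s1_in, p$s1_W, dh, 2L)
  g$s1_W <- cb$dW; g$s1_b <- cb$db
  g
}

#' Per-sample class probabilities for a batch of windows
#'
#' @param model A trained (or freshly built) `ecg_seq2seq`.
#' @param x Numeric matrix (n_windows by seq_len) or a single window vector.
#' @param batch_size Scoring batch size.
#' @return Array (seq_len, n_classes, n_windows) of probabilities; each
#'   per-sample score vector sums to 1.
#' @export
predict_seq2seq <- function(model, x, batch_size = 64) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$cfg$seq_len)
    stop("window length ", ncol(x), " does not match model seq_len ",
         model$cfg$seq_len)
  n <- nrow(x)
  out <- array(0, c(model$cfg$seq_len, model$cfg$n_classes, n))
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1)
    xb <- array(t(x[idx, , drop = FALSE]),
                c(model$cfg$seq_len, 1, length(idx)))
    fw <- seg_forward(model$params, xb, model$cfg, training = FALSE,
                      run_stats = model$run_stats)
    out[, , idx] <- nn_softmax(fw$logits)
  }
  out
}

#' Train the segmentation network
#'
#' Categorical cross-entropy loss (optionally inverse-frequency class
#' weighted), Adam starting at `lr0`, and a reduce-on-plateau schedule: the
#' learning rate is divided by `lr_drop_factor` after `patience` consecutive
#' epochs without validation-accuracy improvement. An 80/20
#' train/validation split is drawn from the provided training indices.
#' Deterministic given `cfg$seed`.
#'
#' @param ds Dataset from [make_training_set()] or [read_window_dataset()].
#' @param cfg A [seq2seq_config()]; `n_classes` must cover the labels.
#' @param train_idx Row indices to train on (default: all).
#' @param verbose Print per-epoch progress.
#' @return A trained `ecg_seq2seq` with a `history` data.frame
#'   (epoch, lr, train_loss, train_acc, val_loss, val_acc).
#' @export
train_seq2seq <- function(ds, cfg, train_idx = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "seq2seq_config"))
  if (is.null(train_idx)) train_idx <- seq_len(nrow(ds$x))
  if (max(ds$y) >= cfg$n_classes)
    stop("labels exceed n_classes; remap the dataset first")
  model <- build_seq2seq(cfg, class_names = ds$class_names)
  set.seed(cfg$seed + 1L)
  n <- length(train_idx)
  n_val <- max(1L, round(cfg$val_frac * n))
  perm <- sample(train_idx)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  K <- cfg$n_classes
  w <- if (cfg$class_weighting)
    nn_class_weights(as.vector(ds$y[tr_idx, ]), K) else rep(1, K)
  present <- sort(unique(as.vector(ds$y[tr_idx, ])))
  if (length(present) < K)
    warning("class(es) absent from training labels: ",
            paste(setdiff(seq_len(K) - 1L, present), collapse = ", "))

  adam <- nn_adam_init(model$params)
  lr <- cfg$lr0
  best_val <- -Inf; stall <- 0L
  hist <- NULL
  L <- cfg$seq_len
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; tn <- 0; tacc <- 0
    for (s in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[s:min(length(ord), s + cfg$batch_size - 1)]
      xb <- array(t(ds$x[bidx, , drop = FALSE]), c(L, 1, length(bidx)))
      yb <- as.vector(t(ds$y[bidx, , drop = FALSE]))
      fw <- seg_forward(model$params, xb, cfg, training = TRUE,
                        run_stats = model$run_stats)
      for (nm in names(fw$bn_batch))
        model$run_stats <- nn_update_run_stats(model$run_stats, nm,
                                               fw$bn_batch[[nm]]$mu,
                                               fw$bn_batch[[nm]]$var)
      sm <- nn_softmax_ce(fw$logits, yb, w)
      grads <- seg_backward(model$params, fw$cache, sm$dlogits, cfg)
      st <- nn_adam_step(model$params, grads, adam, lr)
      model$params <- st$params; adam <- st$state
      pred <- max.col(flatten_lc(sm$probs)) - 1L
      tacc <- tacc + sum(pred == yb)
      tl <- tl + sm$loss * length(yb); tn <- tn + length(yb)
    }
    ev <- seg_eval(model, ds, val_idx, w)
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                   train_loss = tl / tn, train_acc = tacc / tn,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %2d lr %.4g loss %.4f acc %.3f val %.3f",
                      ep, lr, tl / tn, tacc / tn, ev$acc))
    if (ev$acc > best_val + 1e-4) { best_val <- ev$acc; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= cfg$patience) { lr <- lr / cfg$lr_drop_factor; stall <- 0L }
    }
  }
  model$history <- hist
  model
}

seg_eval <- function(model, ds, idx, w = NULL, batch_size = 64) {
  L <- model$cfg$seq_len
  loss <- 0; ntot <- 0; acc <- 0
  for (s in seq(1, length(idx), by = batch_size)) {
    bidx <- idx[s:min(length(idx), s + batch_size - 1)]
    xb <- array(t(ds$x[bidx, , drop = FALSE]), c(L, 1, length(bidx)))
    yb <- as.vector(t(ds$y[bidx, , drop = FALSE]))
    fw <- seg_forward(model$params, xb, model$cfg, training = FALSE,
                      run_stats = model$run_stats)
    sm <- nn_softmax_ce(fw$logits, yb, w)
    pred <- max.col(flatten_lc(sm$probs)) - 1L
    acc <- acc + sum(pred == yb)
    loss <- loss + sm$loss * length(yb); ntot <- ntot + length(yb)
  }
  list(loss = loss / ntot, acc = acc / ntot)
}

#' Cross-validated evaluation of the segmentation network
#'
#' Splits the windows into `cfg$k_folds` disjoint folds (stratified by the
#' dataset's `group` labels when present, so windows from the same archetype
#' are spread evenly and train/test never overlap), trains on k-1 folds and
#' scores per-sample accuracy on the held-out fold.
#'
#' @param ds Dataset (see [train_seq2seq()]).
#' @param cfg A [seq2seq_config()].
#' @param verbose Print per-fold progress.
#' @return List: `fold_acc`, `acc_mean`, `acc_sd`, `confusion` (rows = true
#'   class, aggregated over folds).
#' @export
evaluate_cv <- function(ds, cfg, verbose = FALSE) {
  n <- nrow(ds$x)
  K <- cfg$n_classes
  if (n < cfg$k_folds * K) stop("dataset too small for ", cfg$k_folds, " folds")
  set.seed(cfg$seed + 2L)
  fold <- integer(n)
  strata <- if (!is.null(ds$group)) ds$group else rep("all", n)
  for (g in unique(strata)) {
    idx <- sample(which(strata == g))
    fold[idx] <- rep_len(seq_len(cfg$k_folds), length(idx))
  }
  conf <- matrix(0L, K, K, dimnames = list(true = ds$class_names[seq_len(K)],
                                           pred = ds$class_names[seq_len(K)]))
  fold_acc <- numeric(cfg$k_folds)
  for (kf in seq_len(cfg$k_folds)) {
    te <- which(fold == kf); tr <- which(fold != kf)
    m <- train_seq2seq(ds, cfg, train_idx = tr, verbose = FALSE)
    probs <- predict_seq2seq(m, ds$x[te, , drop = FALSE])
    pred <- matrix(max.col(flatten_lc(probs)) - 1L, nrow = cfg$seq_len)
    truth <- t(ds$y[te, , drop = FALSE])
    fold_acc[kf] <- mean(pred == truth)
    tab <- table(factor(as.vector(truth), levels = 0:(K - 1)),
                 factor(as.vector(pred), levels = 0:(K - 1)))
    conf <- conf + as.matrix(tab)
    if (verbose) message(sprintf("fold %d accuracy %.4f", kf, fold_acc[kf]))
    empty <- ds$class_names[which(rowSums(tab) == 0)]
    if (length(empty))
      message("fold ", kf, ": no test samples for class(es) ",
              paste(empty, collapse = ", "))
  }
  list(fold_acc = fold_acc, acc_mean = mean(fold_acc),
       acc_sd = stats::sd(fold_acc), confusion = conf)
}

#' Annotate a record: per-beat classes and record-level flags
#'
#' Scores non-overlapping 8 s windows with the segmentation model, takes the
#' per-sample argmax, and assigns each detected beat the majority per-sample
#' class within ±300 ms of its R-peak (ties broken toward the class with the
#' higher mean probability in the neighborhood). Record-level flags are
#' raised when any beat is an ectopic class (FB/SVEB/VEB) or when a sustained
#' rhythm class covers more than half of a window.
#'
#' @param model A trained `ecg_seq2seq`.
#' @param rec An [ecg_record()] at 250 Hz.
#' @param beats Beat table (default: [detect_qrs()] on the record).
#' @return List of class `annotation_result`: `per_sample_probs` (L_total by
#'   K), `per_sample_class`, `beat_annotations` (data.frame index, time_s,
#'   class, confidence), `flags` (character vector).
#' @export
annotate <- function(model, rec, beats = NULL) {
  stopifnot(inherits(model, "ecg_seq2seq"), inherits(rec, "ecg_record"))
  if (abs(rec$fs - WORKING_FS) > 1e-9)
    stop("annotate requires a record at ", WORKING_FS, " Hz; resample first")
  L <- model$cfg$seq_len
  n_win <- length(rec$samples) %/% L
  if (n_win == 0) stop("record shorter than one model window")
  xw <- matrix(rec$samples[seq_len(n_win * L)], n_win, L, byrow = TRUE)
  probs <- predict_seq2seq(model, xw)               # (L, K, n_win)
  K <- model$cfg$n_classes
  flat <- matrix(aperm(probs, c(1, 3, 2)), ncol = K)  # (L*n_win, K)
  cls_samp <- max.col(flat) - 1L
  if (is.null(beats)) beats <- detect_qrs(rec)
  half <- as.integer(round(0.3 * rec$fs))
  n_cov <- n_win * L
  ann <- lapply(seq_len(nrow(beats)), function(i) {
    b <- beats$index[i]
    if (b >= n_cov) return(NULL)
    lo <- max(0L, b - half); hi <- min(n_cov - 1L, b + half)
    v <- vote_beat_class(flat, cls_samp, lo, hi)
    data.frame(index = b, time_s = beats$time_s[i], class = v$class,
               confidence = v$confidence)
  })
  ann <- do.call(rbind, ann)
  cn <- model$class_names
  flags <- character(0)
  if (!is.null(ann) && nrow(ann)) {
    ann$class_name <- cn[ann$class + 1L]
    if (any(ann$class_name %in% c("FB", "SVEB", "VEB")))
      flags <- c(flags, "abnormal_beat")
  }
  rhythm_classes <- intersect(c("MI", "HF", "AR"), cn)
  for (wi in seq_len(n_win)) {
    wc <- cls_samp[((wi - 1) * L + 1):(wi * L)]
    frac <- tabulate(wc + 1L, nbins = K) / L
    sustained <- cn[frac > 0.5]
    if (length(intersect(sustained, rhythm_classes)))
      flags <- unique(c(flags, "rhythm"))
  }
  structure(list(per_sample_probs = flat, per_sample_class = cls_samp,
                 beat_annotations = ann, flags = flags,
                 class_names = cn),
            class = "annotation_result")
}

# majority vote over per-sample argmax classes in the half-open 0-based
# sample range [lo, hi]; ties go to the class with the higher mean
# probability over the neighborhood
vote_beat_class <- function(flat_probs, cls_samp, lo, hi) {
  votes <- cls_samp[(lo + 1L):(hi + 1L)]
  tab <- table(votes)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1) {
    mp <- vapply(top, function(k)
      mean(flat_probs[(lo + 1L):(hi + 1L), k + 1L]), 0)
    top <- top[which.max(mp)]
  }
  list(class = top, confidence = max(tab) / length(votes))
}

#' Save / load a model checkpoint
#'
#' Writes a directory holding `config.json` (architecture, class names) and
#' `weights.json` (parameters and batch-norm statistics, full precision).
#'
#' @param model An `ecg_seq2seq` or `activity_resnet`.
#' @param dir Checkpoint directory.
#' @return `dir` invisibly (save); the model (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  type <- class(model)[1]
  cfg <- model$cfg
  jsonlite::write_json(list(type = type, cfg = unclass(cfg),
                            class_names = model$class_names),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wts <- list(params = lapply(model$params, function(p)
    list(dim = dim(p) %||% length(p), data = as.vector(p))),
    run_stats = model$run_stats)
  jsonlite::write_json(wts, file.path(dir, "weights.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  wts <- jsonlite::read_json(file.path(dir, "weights.json"),
                             simplifyVector = TRUE)
  params <- lapply(wts$params, function(p) {
    d <- unlist(p$dim)
    v <- unlist(p$data)
    if (length(d) > 1) array(v, d) else v
  })
  run_stats <- lapply(wts$run_stats, function(s)
    list(mu = unlist(s$mu), var = unlist(s$var)))
  cfg <- meta$cfg
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- if (meta$type == "ecg_seq2seq") "seq2seq_config"
                else "activity_config"
  structure(list(params = params, run_stats = run_stats, cfg = cfg,
                 class_names = meta$class_names, history = NULL),
            class = meta$type)
}
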