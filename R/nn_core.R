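# Minimal 1-D CNN engine backing the segmentation and activity networks.
# Tensors are numeric arrays with dimensions (length, channels, batch).
# Convolution/pooling kernels live in src/nn_ops.cpp; batch normalization,
# activations, up-sampling, the softmax cross-entropy head and the Adam
# optimizer are implemented here. Backpropagation is hand-derived per layer
# and verified against numerical gradients in the test suite.

nn_conv_fwd <- function(x, W, b, stride = 1L) {
  cpp_conv1d_fwd(x, W, b, as.integer(stride))
}

nn_conv_bwd <- function(x, W, dy, stride = 1L) {
  cpp_conv1d_bwd(x, W, dy, as.integer(stride))
}

nn_pool_fwd <- function(x) cpp_maxpool2_fwd(x)
nn_pool_bwd <- function(arg, dy) cpp_maxpool2_bwd(arg, dy)

# flatten (L, C, N) -> ((L*N), C) keeping channel columns
flatten_lc <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2)), ncol = d[2])
}
unflatten_lc <- function(m, d) {
  aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
}

nn_bn_fwd <- function(x, gamma, beta, eps = 1e-5, training = TRUE,
                      run_stats = NULL) {
  if (training || is.null(run_stats)) {
    st <- cpp_bn_stats(x)
    mu <- as.vector(st$mu); v <- as.vector(st$var)
  } else {
    mu <- run_stats$mu; v <- run_stats$var
  }
  r <- cpp_bn_fwd(x, gamma, beta, mu, v, eps)
  list(out = r$out,
       cache = list(x = x, mu = mu, inv = as.vector(r$inv), gamma = gamma),
       mu = mu, var = v)
}

nn_bn_bwd <- function(dy, cache) {
  r <- cpp_bn_bwd(cache$x, cache$mu, cache$inv, cache$gamma, dy)
  list(dx = r$dx, dgamma = as.vector(r$dgamma), dbeta = as.vector(r$dbeta))
}

nn_act_fwd <- function(x, kind) {
  if (kind == "relu") list(out = pmax(x, 0), mask = x > 0)
  else list(out = x, mask = NULL)  # linear
}
nn_act_bwd <- function(dy, act, kind) {
  if (kind == "relu") dy * act$mask else dy
}

nn_upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), , , drop = FALSE]
}
nn_upsample2_bwd <- function(dy) {
  d <- dim(dy)
  odd <- dy[seq(1, d[1], by = 2), , , drop = FALSE]
  even <- dy[seq(2, d[1], by = 2), , , drop = FALSE]
  odd + even
}

nn_concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[3] == db[3])
  out <- array(0, c(da[1], da[2] + db[2], da[3]))
  out[, seq_len(da[2]), ] <- a
  out[, da[2] + seq_len(db[2]), ] <- b
  out
}
nn_concat_bwd <- function(dy, ca) {
  list(da = dy[, seq_len(ca), , drop = FALSE],
       db = dy[, -seq_len(ca), , drop = FALSE])
}

# softmax over channels; y: integer labels in 0..K-1, flattened (L fastest,
# then batch); w: per-class loss weights
nn_softmax_ce <- function(logits, y, w = NULL) {
  d <- dim(logits)
  K <- d[2]
  zm <- flatten_lc(logits)
  zm <- zm - zm[cbind(seq_len(nrow(zm)), max.col(zm, ties.method = "first"))]
  ez <- exp(zm)
  p <- ez / rowSums(ez)
  yi <- as.integer(y) + 1L
  if (is.null(w)) w <- rep(1, K)
  wy <- w[yi]
  eps <- 1e-12
  loss <- -sum(wy * log(p[cbind(seq_along(yi), yi)] + eps)) / sum(wy)
  dz <- p
  dz[cbind(seq_along(yi), yi)] <- dz[cbind(seq_along(yi), yi)] - 1
  dz <- dz * (wy / sum(wy))
  list(loss = loss, probs = unflatten_lc(p, d),
       dlogits = unflatten_lc(dz, d))
}

nn_softmax <- function(logits) {
  d <- dim(logits)
  zm <- flatten_lc(logits)
  zm <- zm - zm[cbind(seq_len(nrow(zm)), max.col(zm, ties.method = "first"))]
  ez <- exp(zm)
  unflatten_lc(ez / rowSums(ez), d)
}

# He-uniform initialization for a (k*Cin, Cout) conv kernel
nn_init_conv <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * cin))
  matrix(stats::runif(k * cin * cout, -lim, lim), k * cin, cout)
}

nn_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

nn_adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# exponential moving average of batch-norm statistics
nn_update_run_stats <- function(run, name, mu, var, momentum = 0.1) {
  if (is.null(run[[name]])) run[[name]] <- list(mu = mu, var = var)
  else {
    run[[name]]$mu <- (1 - momentum) * run[[name]]$mu + momentum * mu
    run[[name]]$var <- (1 - momentum) * run[[name]]$var + momentum * var
  }
  run
}

# inverse-frequency class weights from an integer label vector (0..K-1),
# normalized to mean 1 and capped to avoid degenerate ratios
nn_class_weights <- function(y, K, cap = 20) {
  cnt <- tabulate(as.integer(y) + 1L, nbins = K)
  w <- ifelse(cnt > 0, sum(cnt) / (K * pmax(cnt, 1)), 1)
  w <- pmin(w, cap)
  w / mean(w)
}
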