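# Shared fixtures, built once per test run.

# clean 60 bpm record: metronomic beats, no noise, no modulation
clean60 <- local({
  rec <- NULL
  function() {
    if (is.null(rec))
      rec <<- synth_ecg(ecg_synth_config(
        hr_bpm = 60, hr_sd = 0, resp_mod_depth = 0, rsa_depth = 0,
        noise_sd = 0, wander_amp = 0, duration_s = 60, seed = 301))
    rec
  }
})

# dominant frequency of a series: zero-padded periodogram with parabolic
# peak interpolation (resolution well below one FFT bin)
dominant_freq <- function(x, fs, nfft = 2^14) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(c(x * signal::hanning(n), rep(0, nfft - n))))^2
  half <- 2:(nfft %/% 2)
  pk <- half[which.max(p[half])]
  la <- log(p[pk - 1] + 1e-300); lb <- log(p[pk] + 1e-300)
  lc <- log(p[pk + 1] + 1e-300)
  delta <- 0.5 * (la - lc) / (la - 2 * lb + lc)
  (pk - 1 + delta) / nfft * fs
}

# match detected beat indices to truth within tol samples; returns TP/FP/FN
match_beats <- function(det, truth, tol = 15) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in det) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = length(det) - tp, fn = length(truth) - tp)
}

scheme4 <- c(background = 0L, MI = 1L, SVEB = 2L, VEB = 3L)

# elements of a within tol of any element of b
intersect_within <- function(a, b, tol) {
  a[vapply(a, function(x) any(abs(b - x) <= tol), TRUE)]
}

# small activity classifier trained once and reused across files
act_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      ds <- make_imu_training_set(400, seed = 71)
      m <<- train_activity(ds, activity_config(epochs = 6, seed = 72))
    }
    m
  }
})

# two-class (background / VEB) segmentation model trained once and reused
tiny_veb_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      ds <- make_training_set(160, c(background = .5, VEB = .5), seed = 18,
                              class_scheme = c(background = 0L, VEB = 1L))
      cfg <- seq2seq_config(n_classes = 2, stem_filters = 8, n_blocks = 2,
                            branch_filters = 6, decoder_filters = 12,
                            activation = "relu", lr0 = 0.003, epochs = 6,
                            batch_size = 16, class_weighting = FALSE,
                            seed = 5)
      mm <- train_seq2seq(ds, cfg)
      mm$class_names <- c("background", "VEB")
      m <<- mm
    }
    m
  }
})
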