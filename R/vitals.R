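# QRS detection (Pan-Tompkins variant), heart-rate and ECG-derived
# respiratory-rate estimation, and the windowed SNR metric with median-filter
# noise isolation. All stages are zero-phase (filtfilt / centered moving
# average), so detected events line up with the raw R-peaks, and every
# threshold is relative to the signal itself, which makes the pipeline
# invariant to amplitude scaling and baseline offsets.

#' Detect QRS complexes (Pan-Tompkins variant)
#'
#' Classic stage chain: band-pass 5-15 Hz, five-point derivative, squaring,
#' 150 ms moving-window integration, adaptive dual thresholds with search-back
#' and a 200 ms refractory period. Events are reported at the raw-signal
#' R-peak within ±40 ms of the integrated-energy peak.
#'
#' @param rec An [ecg_record()] (fs >= 100 Hz, duration >= 2 s).
#' @return A data.frame of beat events: `index` (0-based sample), `time_s`,
#'   `amp` (peak-to-trough amplitude in mV within ±60 ms of the R-peak).
#'   Empty (with a warning) for flatline input.
#' @export
detect_qrs <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  if (fs < 100) stop("detect_qrs requires fs >= 100 Hz")
  x <- rec$samples
  n <- length(x)
  if (n < 2 * fs) stop("detect_qrs requires >= 2 s of signal")
  if (sd(x) < .Machine$double.eps * 100) {
    warning("flatline input; no beats detected")
    return(empty_beats())
  }
  x <- x - mean(x)

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  # five-point derivative, zero-phase (symmetric kernel)
  d <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- as.integer(round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  refr <- as.integer(round(0.200 * fs))
  peaks <- local_maxima(integ, min_sep = refr)
  if (!length(peaks)) {
    warning("no integrated-energy peaks found")
    return(empty_beats())
  }

  # adaptive dual thresholds, seeded from the first 2 s
  init <- integ[seq_len(min(n, as.integer(2 * fs)))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- function() npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_avg <- NA_real_
  last_q <- -Inf
  for (p in peaks) {
    if (p - last_q < refr) next
    if (integ[p] > thr1()) {
      # search-back: long gap with a sub-threshold peak above thr1/2
      if (!is.na(rr_avg) && (p - last_q) > 1.66 * rr_avg) {
        cand <- peaks[peaks > last_q + refr & peaks < p - refr]
        cand <- cand[integ[cand] > thr1() / 2]
        if (length(cand)) {
          pb <- cand[which.max(integ[cand])]
          qrs <- c(qrs, pb)
          spki <- 0.25 * integ[pb] + 0.75 * spki
          last_q <- pb
        }
      }
      qrs <- c(qrs, p)
      spki <- 0.125 * integ[p] + 0.875 * spki
      if (length(qrs) >= 2) {
        rrs <- diff(tail(qrs, 8))
        if (length(rrs)) rr_avg <- mean(rrs)
      }
      last_q <- p
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
  }
  qrs <- sort(unique(qrs))
  if (!length(qrs)) {
    warning("no beats above threshold")
    return(empty_beats())
  }

  # refine to the raw-signal R-peak within ±40 ms (largest |deflection|
  # on the band-passed trace, then the matching extremum on the raw trace)
  half <- as.integer(round(0.040 * fs))
  r_idx <- vapply(qrs, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(abs(xf[lo:hi])) - 1L
  }, 0L)
  r_idx <- sort(unique(r_idx))
  # enforce refractory after refinement
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) >= refr)
    r_idx <- r_idx[keep]
  }
  amp_half <- as.integer(round(0.060 * fs))
  amp <- vapply(r_idx, function(p) {
    lo <- max(1L, p - amp_half); hi <- min(n, p + amp_half)
    max(x[lo:hi]) - min(x[lo:hi])
  }, 0)
  data.frame(index = r_idx - 1L, time_s = (r_idx - 1L) / fs, amp = amp)
}

empty_beats <- function() {
  data.frame(index = integer(0), time_s = numeric(0), amp = numeric(0))
}

# indices of local maxima at least min_sep apart (greedy by height)
local_maxima <- function(v, min_sep) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (p in cand)
    if (!length(taken) || all(abs(taken - p) >= min_sep))
      taken <- c(taken, p)
  sort(taken)
}

#' Estimate instantaneous heart rate from beat events
#'
#' Instantaneous HR (60 / RR-interval) is assigned at interval midpoints and
#' interpolated onto a uniform grid with a cubic spline, then clamped to
#' (0, 300) beats per minute.
#'
#' @param beats Beat table from [detect_qrs()] (needs >= 3 beats).
#' @param grid_hz Output grid rate, Hz.
#' @return Data.frame with columns `t` (s) and `hr` (beats per minute).
#' @export
estimate_hr <- function(beats, grid_hz = 4) {
  if (nrow(beats) < 3) stop("insufficient beats (need >= 3)")
  tb <- beats$time_s
  rr <- diff(tb)
  t_mid <- tb[-length(tb)] + rr / 2
  hr <- 60 / rr
  grid <- seq(t_mid[1], t_mid[length(t_mid)], by = 1 / grid_hz)
  s <- stats::spline(t_mid, hr, xout = grid, method = "natural")
  data.frame(t = s$x, hr = pmin(pmax(s$y, 1e-6), 300))
}

#' Estimate respiratory rate from ECG-derived respiration
#'
#' The R-peak amplitude series (amplitude-based EDR) is interpolated to a
#' uniform 4 Hz grid, band-passed to 0.066-0.7 Hz (4-42 breaths per minute),
#' and the respiratory rate is read from the dominant spectral peak of a
#' sliding 30 s window (zero-padded periodogram). Windows without a peak
#' clearly above the in-band floor report `NA`; near-ties are broken toward
#' the previous window's estimate for continuity.
#'
#' @param rec The [ecg_record()] the beats came from (>= 30 s of signal).
#' @param beats Beat table from [detect_qrs()] (needs >= 20 beats).
#' @param step_s Hop between successive 30 s windows, seconds.
#' @return Data.frame with columns `t` (window center, s) and `rr` (breaths
#'   per minute, `NA` where undetectable).
#' @export
estimate_rr <- function(rec, beats, step_s = 5) {
  dur <- length(rec$samples) / rec$fs
  if (dur < 30) stop("estimate_rr requires >= 30 s of signal")
  if (nrow(beats) < 20) stop("insufficient beats (need >= 20)")
  fs_e <- 4
  grid <- seq(beats$time_s[1], beats$time_s[nrow(beats)], by = 1 / fs_e)
  edr <- stats::approx(beats$time_s, beats$amp, xout = grid)$y
  edr <- edr - mean(edr)
  bp <- signal::butter(2, c(0.066, 0.7) / (fs_e / 2), type = "pass")
  edr_f <- signal::filtfilt(bp, edr)

  win <- 30 * fs_e
  if (length(edr_f) < win) stop("too little usable EDR signal")
  starts <- seq(1, length(edr_f) - win + 1, by = step_s * fs_e)
  nfft <- 4096
  freqs <- (0:(nfft - 1)) / nfft * fs_e
  band <- freqs >= 0.066 & freqs <= 0.7
  prev <- NA_real_
  out <- lapply(starts, function(s) {
    seg <- edr_f[s:(s + win - 1)] * signal::hanning(win)
    p <- Mod(stats::fft(c(seg, rep(0, nfft - win))))^2
    pb <- p[band]; fb <- freqs[band]
    pk <- which.max(pb)
    # respiration-driven peaks exceed the in-band floor by 2-3 orders of
    # magnitude; an unmodulated amplitude series stays within one order
    detectable <- pb[pk] > 50 * stats::median(pb)
    rr <- NA_real_
    if (detectable) {
      # near-ties (within 5% power) resolve toward the previous estimate
      near <- which(pb > 0.95 * pb[pk])
      near <- near[vapply(near, function(i)
        i <= 2 || i >= length(pb) - 1 ||
          (pb[i] >= pb[i - 1] && pb[i] >= pb[i + 1]), TRUE)]
      pick <- if (!is.na(prev) && length(near) > 1)
        near[which.min(abs(fb[near] * 60 - prev))] else pk
      rr <- fb[pick] * 60
      prev <<- rr
    }
    data.frame(t = beats$time_s[1] + (s - 1) / fs_e + 15, rr = rr)
  })
  do.call(rbind, out)
}

#' Signal-to-noise ratio in decibels from amplitude ratio
#'
#' `SNR_dB = 10 log10((A_signal / A_noise)^2)`.
#' @param a_signal Mean QRS-complex amplitude.
#' @param a_noise Mean noise amplitude (same units).
#' @return SNR in dB.
#' @export
snr_db <- function(a_signal, a_noise) 10 * log10((a_signal / a_noise)^2)

#' Windowed ECG signal-to-noise ratio
#'
#' The recording is split into 8 s windows. Per window, QRS complexes are
#' detected and their mean peak-to-trough amplitude is `A_signal`. Each
#' P-QRS-T complex is then excised (linear interpolation bridges the gap) and
#' an order-99 running-median filter isolates what is left — the baseline
#' noise floor, free of the narrow cardiac deflections. `A_noise` is the mean
#' absolute deviation of that floor from its median level, measured over the
#' samples between complexes. The window SNR is
#' `10 log10((A_signal/A_noise)^2)` and the report averages over windows.
#' Windows without detectable beats are skipped. Every stage is homogeneous
#' in amplitude and centered, so the metric is invariant to scaling and to
#' constant offsets.
#'
#' @param rec An [ecg_record()] of at least 8 s.
#' @param win_s Window length, seconds.
#' @param median_order Running-median kernel length in samples.
#' @return List of class `snr_report`: `per_window_db`, `mean_db`,
#'   `a_signal`, `a_noise`.
#' @export
snr <- function(rec, win_s = 8, median_order = 99) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  L <- as.integer(round(win_s * fs))
  if (length(rec$samples) < L) stop("snr requires >= ", win_s, " s of signal")
  n_win <- length(rec$samples) %/% L
  per <- a_sig <- a_noi <- numeric(0)
  for (k in seq_len(n_win)) {
    xw <- rec$samples[((k - 1) * L + 1):(k * L)]
    wrec <- ecg_record(xw, fs = fs)
    beats <- tryCatch(suppressWarnings(detect_qrs(wrec)),
                      error = function(e) empty_beats())
    if (!nrow(beats)) next
    a_signal <- mean(beats$amp)
    # excise whole complexes (P onset to T offset), shrinking the span at
    # high rates so some baseline always remains between beats
    ibi <- if (nrow(beats) > 1) median(diff(beats$time_s)) else 0.8
    lo_s <- min(0.25, 0.4 * ibi)
    hi_s <- min(0.45, 0.5 * ibi)
    xp <- xw
    keep <- rep(TRUE, L)
    for (b in beats$index + 1L) {
      lo <- max(1L, b - as.integer(round(lo_s * fs)))
      hi <- min(L, b + as.integer(round(hi_s * fs)))
      xp[lo:hi] <- seq(xp[lo], xp[hi], length.out = hi - lo + 1L)
      keep[lo:hi] <- FALSE
    }
    if (sum(keep) < 50) keep <- rep(TRUE, L)
    sm <- stats::runmed(xp, k = median_order, endrule = "median")
    noise <- sm - stats::median(sm)
    a_noise <- mean(abs(noise[keep]))
    if (a_noise <= 0) next
    per <- c(per, snr_db(a_signal, a_noise))
    a_sig <- c(a_sig, a_signal); a_noi <- c(a_noi, a_noise)
  }
  if (!length(per)) stop("no windows with detectable beats")
  structure(list(per_window_db = per, mean_db = mean(per),
                 a_signal = mean(a_sig), a_noise = mean(a_noi)),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> mean %.2f dB over %d windows (A_signal %.3f, A_noise %.4f)\n",
              x$mean_db, length(x$per_window_db), x$a_signal, x$a_noise))
  invisible(x)
}
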