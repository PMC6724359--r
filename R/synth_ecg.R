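# Synthetic single-lead ECG with exact ground truth. Beats are placed by a
# renewal process and rendered from a Gaussian-sum P-QRS-T template; ectopic
# beats get their own morphology and timing; respiration modulates both
# R-amplitude and beat intervals; baseline wander and white noise are added
# on top. Every generated record carries its true beat table, so downstream
# detectors and networks can be scored against construction.

#' Configuration for the synthetic ECG generator
#'
#' @param hr_bpm Mean heart rate, beats per minute (20-250).
#' @param hr_sd Beat-interval jitter, seconds (SD of the renewal process).
#' @param rr_brpm Respiratory rate, breaths per minute (4-60).
#' @param resp_mod_depth Fractional R-amplitude modulation at the respiratory
#'   frequency (the signal ECG-derived respiration recovers).
#' @param rsa_depth Fractional beat-interval modulation at the respiratory
#'   frequency (respiratory sinus arrhythmia).
#' @param ectopic List of `c(class, rate)` pairs or a named numeric vector of
#'   per-minute ectopic rates, e.g. `c(VEB = 4)`. Supported classes: VEB,
#'   SVEB, FB.
#' @param noise_sd Additive white-noise SD in mV.
#' @param wander_amp Baseline-wander amplitude in mV.
#' @param wander_hz Baseline-wander frequency in Hz; `NULL` ties it to the
#'   respiratory frequency (wander in resting recordings is mostly
#'   respiration-driven).
#' @param rhythm Optional record-level rhythm class (`"MI"`, `"HF"`, `"AR"`)
#'   that also switches the beat morphology to the matching variant.
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return A list of class `ecg_synth_config`.
#' @export
ecg_synth_config <- function(hr_bpm = 72, hr_sd = 0.03, rr_brpm = 15,
                             resp_mod_depth = 0.15, rsa_depth = 0.05,
                             ectopic = NULL, noise_sd = 0.03,
                             wander_amp = 0.1, wander_hz = NULL,
                             rhythm = NULL, duration_s = 60,
                             fs = WORKING_FS, seed = 1L) {
  if (hr_bpm < 20 || hr_bpm > 250) stop("hr_bpm must be in [20, 250]")
  if (rr_brpm < 4 || rr_brpm > 60) stop("rr_brpm must be in [4, 60]")
  if (hr_sd < 0 || noise_sd < 0 || wander_amp < 0) stop("rates must be >= 0")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(ectopic)) {
    if (is.numeric(ectopic) && !is.null(names(ectopic)))
      ectopic <- lapply(names(ectopic), function(k) list(cls = k, rate = ectopic[[k]]))
    if (any(vapply(ectopic, function(e) e$rate, 0) < 0))
      stop("ectopic rates must be >= 0")
  }
  structure(list(hr_bpm = hr_bpm, hr_sd = hr_sd, rr_brpm = rr_brpm,
                 resp_mod_depth = resp_mod_depth, rsa_depth = rsa_depth,
                 ectopic = ectopic, noise_sd = noise_sd,
                 wander_amp = wander_amp, wander_hz = wander_hz,
                 rhythm = rhythm, duration_s = duration_s, fs = fs,
                 seed = as.integer(seed)),
            class = "ecg_synth_config")
}

# Gaussian-sum beat templates: columns amplitude (mV), center (s, rel. R),
# width (s). Rows P, Q, R, S, T. Baseline morphology approximates a
# precordial V2 beat; variants alter the features that distinguish each
# class (ST segment, QRS width, P wave).
ecg_beat_template <- function(variant = c("normal", "mi", "hf", "fb",
                                          "veb", "sveb")) {
  variant <- match.arg(variant)
  base <- rbind(
    P = c(0.15, -0.22, 0.025),
    Q = c(-0.20, -0.035, 0.010),
    R = c(1.20, 0.000, 0.012),
    S = c(-0.35, 0.035, 0.012),
    T = c(0.35, 0.30, 0.060))
  colnames(base) <- c("amp", "mu", "sd")
  out <- switch(variant,
    normal = base,
    # ST-segment elevation with a tall merged T wave
    mi = rbind(base[1:4, ], ST = c(0.30, 0.15, 0.055), T = c(0.50, 0.32, 0.07)),
    # low-voltage, mildly widened complexes
    hf = {
      m <- base; m[, "amp"] <- m[, "amp"] * 0.55
      m[c("Q", "R", "S"), "sd"] <- m[c("Q", "R", "S"), "sd"] * 1.5; m
    },
    # fusion: intermediate width and amplitude, attenuated P
    fb = rbind(P = c(0.06, -0.22, 0.025), Q = c(-0.25, -0.05, 0.02),
               R = c(0.90, 0, 0.025), S = c(-0.45, 0.05, 0.022),
               T = c(0.25, 0.30, 0.06)),
    # ventricular ectopic: wide bizarre QRS, no P, discordant T
    veb = rbind(Q = c(-0.80, -0.05, 0.030), R = c(1.50, 0.01, 0.045),
                S = c(-0.60, 0.09, 0.035), T = c(-0.45, 0.34, 0.07)),
    # supraventricular ectopic: narrow QRS, absent P, slightly small R
    sveb = rbind(Q = c(-0.18, -0.035, 0.010), R = c(1.00, 0, 0.012),
                 S = c(-0.30, 0.035, 0.012), T = c(0.30, 0.30, 0.06)))
  colnames(out) <- c("amp", "mu", "sd")
  out
}

render_beat_template <- function(tmpl, t) {
  v <- numeric(length(t))
  for (r in seq_len(nrow(tmpl)))
    v <- v + tmpl[r, "amp"] * exp(-0.5 * ((t - tmpl[r, "mu"]) / tmpl[r, "sd"])^2)
  v
}

#' Generate a synthetic ECG record with exact beat labels
#'
#' @param cfg An [ecg_synth_config()].
#' @return An [ecg_record()] whose `beat_labels` are the true R-peak sample
#'   indices and classes (`"N"`, `"V"`, `"S"`, `"F"`), and whose
#'   `rhythm_label` echoes `cfg$rhythm`.
#' @export
synth_ecg <- function(cfg) {
  stopifnot(inherits(cfg, "ecg_synth_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs; dur <- cfg$duration_s
  f_resp <- cfg$rr_brpm / 60
  mean_ibi <- 60 / cfg$hr_bpm

  # renewal process with respiratory sinus arrhythmia
  n_max <- ceiling(dur / mean_ibi * 2) + 10
  ibis <- pmax(stats::rnorm(n_max, mean_ibi, cfg$hr_sd), 0.25)
  t_beats <- cumsum(ibis)
  t_beats <- t_beats[t_beats < dur + mean_ibi]
  if (cfg$rsa_depth > 0) {
    # modulate each interval by the respiratory phase at its start
    t0 <- c(0, head(t_beats, -1))
    t_beats <- cumsum(diff(c(0, t_beats)) *
                        (1 + cfg$rsa_depth * sin(2 * pi * f_resp * t0)))
  }
  t_beats <- t_beats[t_beats > 0.3 & t_beats < dur - 0.3]
  cls <- rep("N", length(t_beats))

  # ectopic beats replace the nearest scheduled normal beat; ventricular
  # ectopics fire prematurely and keep the following beat (compensatory pause)
  if (!is.null(cfg$ectopic)) {
    for (e in cfg$ectopic) {
      n_ect <- stats::rpois(1, e$rate * dur / 60)
      if (n_ect == 0) next
      t_ect <- sort(stats::runif(n_ect, 1, dur - 1))
      sym <- switch(toupper(e$cls), VEB = "V", SVEB = "S", FB = "F",
                    stop("unsupported ectopic class: ", e$cls))
      for (te in t_ect) {
        i <- which.min(abs(t_beats - te))
        if (cls[i] != "N") next
        if (sym %in% c("V", "S") && i > 1) {
          # premature: fires at ~60% of the preceding interval
          t_beats[i] <- t_beats[i - 1] + 0.6 * (t_beats[i] - t_beats[i - 1])
        }
        cls[i] <- sym
      }
    }
  }

  n <- as.integer(round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  rhythm_variant <- if (!is.null(cfg$rhythm))
    switch(cfg$rhythm, MI = "mi", HF = "hf", AR = "normal", "normal")
  else "normal"
  tmpl_cache <- list()
  for (i in seq_along(t_beats)) {
    variant <- switch(cls[i], N = rhythm_variant, V = "veb", S = "sveb",
                      F = "fb")
    if (is.null(tmpl_cache[[variant]]))
      tmpl_cache[[variant]] <- ecg_beat_template(variant)
    tmpl <- tmpl_cache[[variant]]
    amp_scale <- 1 + cfg$resp_mod_depth * sin(2 * pi * f_resp * t_beats[i])
    lo <- max(1L, as.integer(floor((t_beats[i] - 0.45) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((t_beats[i] + 0.55) * fs)) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] +
      amp_scale * render_beat_template(tmpl, t[idx] - t_beats[i])
  }

  w_hz <- if (is.null(cfg$wander_hz)) f_resp else cfg$wander_hz
  if (cfg$wander_amp > 0)
    x <- x + cfg$wander_amp * sin(2 * pi * w_hz * t + stats::runif(1, 0, 2 * pi))
  if (cfg$noise_sd > 0)
    x <- x + stats::rnorm(n, 0, cfg$noise_sd)

  idx_beats <- as.integer(round(t_beats * fs))
  keep <- idx_beats >= 0 & idx_beats < n
  ecg_record(x, fs = fs, lead = "V2",
             beat_labels = data.frame(index = idx_beats[keep],
                                      cls = cls[keep]),
             rhythm_label = cfg$rhythm)
}

#' Build a labeled window training set from synthetic records
#'
#' Draws window archetypes from `class_mix`, generates one synthetic record
#' per window with the matching morphology/rhythm/ectopy, and expands labels
#' per sample. Archetypes: `background` (normal sinus), `MI`, `HF` (rhythm
#' classes painted over the whole window), `FB`, `SVEB`, `VEB` (ectopic beats
#' painted over ±300 ms neighborhoods).
#'
#' @param n_windows Number of 8 s windows to generate.
#' @param class_mix Named numeric vector of archetype proportions
#'   (must sum to 1), e.g. `c(background=.25, MI=.25, VEB=.25, SVEB=.25)`.
#' @param seed Integer seed.
#' @param class_scheme Label map; defaults to the 9-class scheme.
#' @param hr_range Heart-rate range sampled per window.
#' @param ectopic_rate Per-minute rate used for ectopic archetypes (about
#'   three ectopic beats per 8 s window at the default).
#' @return Dataset list: `x` (n-by-2000), `y` (n-by-2000 int), `fs`,
#'   `class_names`, `group` (archetype per window).
#' @export
make_training_set <- function(n_windows, class_mix, seed = 1L,
                              class_scheme = ecg_class_scheme(),
                              hr_range = c(60, 90), ectopic_rate = 24) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (n_windows < length(class_mix))
    stop("n_windows must be >= number of archetypes")
  set.seed(seed)
  arch <- sample(rep(names(class_mix),
                     diff(round(cumsum(c(0, class_mix)) * n_windows))))
  L <- as.integer(8 * WORKING_FS)
  x <- matrix(0, n_windows, L)
  y <- matrix(0L, n_windows, L)
  for (i in seq_len(n_windows)) {
    a <- arch[i]
    hr <- stats::runif(1, hr_range[1], hr_range[2])
    cfg <- ecg_synth_config(
      hr_bpm = hr, duration_s = 10, seed = sample.int(2^31 - 1, 1),
      rhythm = if (a %in% c("MI", "HF", "AR")) a else NULL,
      ectopic = if (a %in% c("VEB", "SVEB", "FB"))
        stats::setNames(ectopic_rate, a) else NULL)
    rec <- synth_ecg(cfg)
    w <- make_windows(rec, win_s = 8, class_scheme = class_scheme)[[1]]
    x[i, ] <- w$x
    y[i, ] <- w$y
  }
  list(x = x, y = y, fs = WORKING_FS,
       class_names = names(class_scheme), group = arch)
}
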