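# Synthetic 6-axis IMU streams for the five activity classes. The device sits
# on the chest: gravity loads the z accelerometer axis at rest. Gait shows up
# as cadence-locked bursts on the vertical axis with weaker lateral coupling;
# stairs add a slow pitch-gyro oscillation; a fall is a single high-magnitude
# transient followed by an orientation change and stillness.

#' Configuration for the synthetic IMU generator
#'
#' @param activity One of `"idle"`, `"walk"`, `"stairs"`, `"run"`, `"fall"`.
#' @param duration_s Stream length in seconds.
#' @param fs Sampling rate, Hz (models run at 50 Hz).
#' @param seed Integer seed.
#' @param cadence_hz Step frequency; default is activity-specific
#'   (walk 1.8 Hz, stairs 1.5 Hz, run 2.8 Hz).
#' @param amp Vertical acceleration burst amplitude in m s^-2; default is
#'   activity-specific.
#' @param noise_sd Accelerometer noise SD (m s^-2).
#' @param gyro_noise_sd Gyroscope noise SD (deg s^-1).
#' @param fall_time_s Time of the fall transient (fall activity only).
#' @return A list of class `imu_synth_config`.
#' @export
imu_synth_config <- function(activity, duration_s = 60, fs = 50, seed = 1L,
                             cadence_hz = NULL, amp = NULL,
                             noise_sd = 0.15, gyro_noise_sd = 1.5,
                             fall_time_s = NULL) {
  activities <- c("idle", "walk", "stairs", "run", "fall")
  if (!activity %in% activities)
    stop("unknown activity: ", activity, " (expected one of ",
         paste(activities, collapse = ", "), ")")
  if (duration_s <= 0) stop("duration_s must be positive")
  defaults <- list(idle = c(0, 0), walk = c(1.8, 2.0), stairs = c(1.5, 2.5),
                   run = c(2.8, 5.0), fall = c(0, 0))
  d <- defaults[[activity]]
  structure(list(activity = activity, duration_s = duration_s, fs = fs,
                 seed = as.integer(seed),
                 cadence_hz = if (is.null(cadence_hz)) d[1] else cadence_hz,
                 amp = if (is.null(amp)) d[2] else amp,
                 noise_sd = noise_sd, gyro_noise_sd = gyro_noise_sd,
                 fall_time_s = fall_time_s),
            class = "imu_synth_config")
}

G_MSS <- 9.80665  # standard gravity, m s^-2

#' Generate a synthetic IMU record
#'
#' @param cfg An [imu_synth_config()].
#' @return An [imu_record()] with `activity` set to the generating class.
#' @export
synth_imu <- function(cfg) {
  stopifnot(inherits(cfg, "imu_synth_config"))
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  acc <- cbind(ax = numeric(n), ay = numeric(n), az = rep(G_MSS, n))
  gyro <- matrix(0, n, 3, dimnames = list(NULL, c("gx", "gy", "gz")))

  add_gait <- function(acc, gyro, cadence, amp) {
    ph <- stats::runif(1, 0, 2 * pi)
    # impact-like vertical bursts: rectified-sine harmonic stack
    s <- sin(2 * pi * cadence * t + ph)
    burst <- amp * (pmax(s, 0)^2 + 0.3 * sin(4 * pi * cadence * t + ph))
    acc[, "az"] <- acc[, "az"] + burst
    acc[, "ax"] <- acc[, "ax"] + 0.35 * amp * sin(2 * pi * cadence / 2 * t + ph)
    acc[, "ay"] <- acc[, "ay"] + 0.2 * amp * sin(2 * pi * cadence * t + ph + 1)
    gyro[, "gy"] <- gyro[, "gy"] + 12 * amp * sin(2 * pi * cadence * t + ph + 0.5)
    gyro[, "gz"] <- gyro[, "gz"] + 5 * amp * sin(2 * pi * cadence / 2 * t + ph)
    list(acc = acc, gyro = gyro)
  }

  if (cfg$activity %in% c("walk", "run")) {
    g <- add_gait(acc, gyro, cfg$cadence_hz, cfg$amp)
    acc <- g$acc; gyro <- g$gyro
  } else if (cfg$activity == "stairs") {
    g <- add_gait(acc, gyro, cfg$cadence_hz, cfg$amp)
    acc <- g$acc; gyro <- g$gyro
    # slow pitch oscillation from the stair climb posture cycle
    gyro[, "gx"] <- gyro[, "gx"] +
      15 * sin(2 * pi * cfg$cadence_hz / 4 * t + stats::runif(1, 0, 2 * pi))
    acc[, "ax"] <- acc[, "ax"] + 1.2 * sin(2 * pi * cfg$cadence_hz / 4 * t)
  } else if (cfg$activity == "fall") {
    t_fall <- if (is.null(cfg$fall_time_s))
      stats::runif(1, 0.2 * cfg$duration_s, 0.8 * cfg$duration_s)
    else cfg$fall_time_s
    i0 <- as.integer(round(t_fall * cfg$fs)) + 1L
    dur_imp <- as.integer(round(0.3 * cfg$fs))
    idx <- i0:min(n, i0 + dur_imp - 1L)
    ph <- pi * seq(0, 1, length.out = length(idx))
    # impact transient: peak magnitude ~4 g, guaranteed > 3 g once
    acc[idx, "ax"] <- acc[idx, "ax"] + 2.5 * G_MSS * sin(ph)
    acc[idx, "az"] <- acc[idx, "az"] + 3.2 * G_MSS * sin(ph)
    gyro[idx, "gx"] <- gyro[idx, "gx"] + 250 * sin(ph)
    # orientation change: gravity migrates from z to x (lying down)
    after <- idx[length(idx)] < n
    if (after) {
      rest <- (idx[length(idx)] + 1L):n
      blend <- pmin((rest - rest[1]) / (0.5 * cfg$fs), 1)
      acc[rest, "az"] <- G_MSS * (1 - blend)
      acc[rest, "ax"] <- G_MSS * blend
    }
  }

  acc <- acc + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), n, 3)
  gyro <- gyro + matrix(stats::rnorm(3 * n, 0, cfg$gyro_noise_sd), n, 3)
  rec <- imu_record(acc, gyro, fs = cfg$fs, activity = cfg$activity)
  rec$fall_time_s <- if (cfg$activity == "fall") t_fall else NULL
  rec
}

#' Build a labeled IMU window training set
#'
#' Generates one stream per activity draw and cuts it into fixed windows.
#'
#' @param n_windows Total number of windows.
#' @param class_mix Named proportions over the five activities (sum to 1);
#'   default uniform.
#' @param seed Integer seed.
#' @param window_s Window length in seconds.
#' @param fs Sampling rate, Hz.
#' @return List with `x` (n-by-(window_s*fs)-by-6 array), `label` (factor),
#'   `fs`, `classes`.
#' @export
make_imu_training_set <- function(n_windows,
                                  class_mix = c(idle = .2, walk = .2,
                                                stairs = .2, run = .2,
                                                fall = .2),
                                  seed = 1L, window_s = 4, fs = 50) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  set.seed(seed)
  arch <- sample(rep(names(class_mix),
                     diff(round(cumsum(c(0, class_mix)) * n_windows))))
  L <- as.integer(window_s * fs)
  x <- array(0, c(n_windows, L, 6))
  for (i in seq_len(n_windows)) {
    a <- arch[i]
    cfg <- imu_synth_config(a, duration_s = window_s + 1, fs = fs,
                            seed = sample.int(2^31 - 1, 1),
                            fall_time_s = if (a == "fall")
                              stats::runif(1, 0.8, window_s - 0.8) else NULL)
    rec <- synth_imu(cfg)
    x[i, , ] <- cbind(rec$acc, rec$gyro)[seq_len(L), ]
  }
  list(x = x, label = factor(arch, levels = names(class_mix)),
       fs = fs, classes = names(class_mix))
}
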