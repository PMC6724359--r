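test_that("clean 60 bpm record has metronomic beats", {
  rec <- clean60()
  nb <- nrow(rec$beat_labels)
  expect_true(abs(nb - 60) <= 1)
  rrs <- diff(rec$beat_labels$index) / rec$fs
  expect_true(all(abs(rrs - 1.0) < 0.01))
})

test_that("generator is bit-reproducible under a fixed seed", {
  cfg <- ecg_synth_config(ectopic = c(VEB = 6), duration_s = 60, seed = 42)
  a <- synth_ecg(cfg)
  b <- synth_ecg(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$beat_labels, b$beat_labels)
  i1 <- synth_imu(imu_synth_config("walk", seed = 5))
  i2 <- synth_imu(imu_synth_config("walk", seed = 5))
  expect_identical(i1$acc, i2$acc)
  expect_identical(i1$gyro, i2$gyro)
})

test_that("ectopic beats appear at the configured Poisson rate", {
  counts <- vapply(1:8, function(s) {
    rec <- synth_ecg(ecg_synth_config(ectopic = c(VEB = 6), duration_s = 60,
                                      seed = 1000L + s))
    sum(rec$beat_labels$cls == "V")
  }, 0L)
  # mean 6/min; allow generous Monte-Carlo slack over 8 records
  expect_gt(mean(counts), 3)
  expect_lt(mean(counts), 9)
  # same seed reproduces the same count
  again <- sum(synth_ecg(ecg_synth_config(ectopic = c(VEB = 6),
                                          duration_s = 60,
                                          seed = 1001L))$beat_labels$cls == "V")
  expect_identical(again, counts[1])
})

test_that("respiratory modulation puts the R-amplitude peak at rr/60 Hz", {
  rec <- synth_ecg(ecg_synth_config(hr_bpm = 72, rr_brpm = 15,
                                    resp_mod_depth = 0.2, noise_sd = 0,
                                    wander_amp = 0, duration_s = 120,
                                    seed = 8))
  idx <- rec$beat_labels$index + 1L
  amps <- rec$samples[idx]
  tb <- rec$beat_labels$index / rec$fs
  grid <- seq(tb[1], tb[length(tb)], by = 0.25)
  series <- approx(tb, amps, xout = grid)$y
  f <- dominant_freq(series, 4)
  expect_lt(abs(f - 0.25), 0.02)
})

test_that("ground-truth beats agree with painted label regions", {
  rec <- synth_ecg(ecg_synth_config(ectopic = c(VEB = 8), duration_s = 60,
                                    seed = 12))
  y <- expand_labels(rec)
  runs <- rle(y == ecg_class_scheme()[["VEB"]])
  n_regions <- sum(runs$values)
  n_veb <- sum(rec$beat_labels$cls == "V")
  # painted regions can merge only if two VEBs fall within 600 ms — absent
  # at this rate
  expect_identical(n_regions, n_veb)
})

test_that("training-set archetype mix is honored within one window", {
  ds <- make_training_set(100, c(background = 1 / 3, MI = 1 / 3, VEB = 1 / 3),
                          seed = 3, class_scheme = scheme4)
  counts <- table(ds$group)
  expect_true(all(abs(counts - 100 / 3) <= 1))
  expect_identical(dim(ds$x), c(100L, 2000L))
  # same seed -> identical dataset
  ds2 <- make_training_set(100, c(background = 1 / 3, MI = 1 / 3, VEB = 1 / 3),
                           seed = 3, class_scheme = scheme4)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$y, ds2$y)
  # all-background mix -> all labels zero
  ds0 <- make_training_set(5, c(background = 1), seed = 3,
                           class_scheme = scheme4)
  expect_true(all(ds0$y == 0L))
  expect_error(make_training_set(2, c(background = .5, MI = .3, VEB = .2)),
               ">=")
})

test_that("idle IMU stream sits at 1 g; cadence separates walk from run", {
  idle <- synth_imu(imu_synth_config("idle", duration_s = 30, seed = 4,
                                     noise_sd = 1e-4))
  mag <- sqrt(rowSums(idle$acc^2))
  expect_true(all(abs(mag - 9.80665) < 0.01))

  walk <- synth_imu(imu_synth_config("walk", duration_s = 60, seed = 4))
  run <- synth_imu(imu_synth_config("run", duration_s = 60, seed = 4))
  f_walk <- dominant_freq(sqrt(rowSums(walk$acc^2)), 50)
  f_run <- dominant_freq(sqrt(rowSums(run$acc^2)), 50)
  expect_gt(f_run, f_walk)
  expect_lt(abs(f_walk - 1.8), 0.4)
  expect_lt(abs(f_run - 2.8), 0.4)
})

test_that("a fall produces exactly one >3 g transient then stillness", {
  rec <- synth_imu(imu_synth_config("fall", duration_s = 30, seed = 6,
                                    fall_time_s = 10))
  mag <- sqrt(rowSums(rec$acc^2))
  over <- rle(mag > 3 * 9.80665)
  expect_identical(sum(over$values), 1L)
  peak_t <- which.max(mag) / rec$fs
  expect_lt(abs(peak_t - 10), 0.5)
  # orientation change: gravity ends up on the x axis
  late <- rec$acc[(25 * 50):(30 * 50 - 1), ]
  expect_lt(abs(mean(late[, "ax"]) - 9.80665), 0.5)
  expect_lt(abs(mean(late[, "az"])), 0.5)
  expect_error(synth_imu(imu_synth_config("swim")), "unknown activity")
})
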