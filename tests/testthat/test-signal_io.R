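test_that("CSV round-trip preserves samples and beat labels", {
  rec <- ecg_record(sin(2 * pi * 1.2 * (0:2499) / 250), fs = 250,
                    beat_labels = data.frame(index = c(100L, 600L, 1400L),
                                             cls = c("N", "V", "N")))
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_ecg_csv(rec, path)
  back <- read_ecg(path)
  expect_s3_class(back, "ecg_record")
  expect_length(back$samples, 2500)
  expect_equal(back$fs, 250)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$beat_labels$index, c(100L, 600L, 1400L))
  expect_equal(back$beat_labels$cls, c("N", "V", "N"))
})

test_that("record invariants are enforced", {
  expect_error(ecg_record(c(1, NA, 3), fs = 250), "finite")
  expect_error(ecg_record(1:10, fs = -1), "positive")
  expect_error(ecg_record(1:10, fs = 250,
                          beat_labels = data.frame(index = c(5L, 5L),
                                                   cls = c("N", "N"))),
               "strictly increasing")
  expect_error(ecg_record(1:10, fs = 250,
                          beat_labels = data.frame(index = 99L, cls = "N")),
               "out of range")
})

test_that("resampling converts rate, length and beat indices", {
  # 8 s at 1000 Hz -> 2000 samples at the 250 Hz working rate
  t <- (0:7999) / 1000
  rec <- ecg_record(sin(2 * pi * 5 * t), fs = 1000,
                    beat_labels = data.frame(index = c(1000L, 4000L),
                                             cls = c("N", "N")))
  out <- resample_ecg(rec, 250)
  expect_equal(length(out$samples), 2000)
  expect_equal(out$fs, 250)
  expect_equal(out$beat_labels$index, c(250L, 1000L))

  # identity
  expect_identical(resample_ecg(rec, 1000), rec)

  # 257 -> 250 Hz preserves a 5 Hz tone's frequency and amplitude within 1%
  t2 <- (0:(257 * 20 - 1)) / 257
  rec2 <- ecg_record(sin(2 * pi * 5 * t2), fs = 257)
  out2 <- resample_ecg(rec2, 250)
  f <- dominant_freq(out2$samples, 250)
  expect_lt(abs(f - 5) / 5, 0.01)
  core <- out2$samples[500:4500]  # away from filter edges
  expect_lt(abs(max(core) - 1), 0.01)
})

test_that("down-up resampling round trip preserves frequency to <0.1%", {
  t <- (0:(1000 * 12 - 1)) / 1000
  rec <- ecg_record(sin(2 * pi * 17 * t), fs = 1000)
  back <- resample_ecg(resample_ecg(rec, 250), 1000)
  f <- dominant_freq(back$samples, 1000)
  expect_lt(abs(f - 17) / 17, 0.001)
})

test_that("windowing yields fixed 2000-sample windows, dropping partials", {
  rec <- synth_ecg(ecg_synth_config(duration_s = 60, seed = 7))
  w <- make_windows(rec)
  expect_length(w, 7)                     # floor(60 / 8)
  expect_true(all(vapply(w, function(x) length(x$x), 0L) == 2000))
  expect_true(all(vapply(w, function(x) length(x$y), 0L) == 2000))

  rec8 <- synth_ecg(ecg_synth_config(duration_s = 8, seed = 7))
  expect_length(make_windows(rec8), 1)

  rec79 <- synth_ecg(ecg_synth_config(duration_s = 7.9, seed = 7))
  expect_warning(w79 <- make_windows(rec79), "shorter")
  expect_length(w79, 0)
})

test_that("windowed labels reconstruct the expanded label vector", {
  rec <- synth_ecg(ecg_synth_config(duration_s = 30, seed = 9,
                                    ectopic = c(VEB = 10)))
  y_all <- expand_labels(rec)
  w <- make_windows(rec)
  y_cat <- unlist(lapply(w, `[[`, "y"))
  expect_identical(y_cat, y_all[seq_along(y_cat)])
})

test_that("label expansion paints beats over rhythm over background", {
  n <- 2500L
  scheme <- ecg_class_scheme()
  # zero annotations -> all background
  rec0 <- ecg_record(numeric(n), fs = 250)
  expect_identical(expand_labels(rec0), rep(0L, n))

  # one VEB at 1000 with the default ±300 ms neighborhood -> 151 samples
  rec1 <- ecg_record(numeric(n), fs = 250,
                     beat_labels = data.frame(index = 1000L, cls = "V"))
  y1 <- expand_labels(rec1)
  expect_identical(sum(y1 == scheme[["VEB"]]), 151L)
  expect_identical(which(y1 == scheme[["VEB"]]), 926:1076)

  # rhythm MI everywhere except an FB beat's neighborhood; verified against
  # a brute-force per-sample paint
  rec2 <- ecg_record(numeric(n), fs = 250, rhythm_label = "MI",
                     beat_labels = data.frame(index = c(400L, 1200L),
                                              cls = c("N", "F")))
  y2 <- expand_labels(rec2)
  brute <- rep(scheme[["MI"]], n)
  brute[(1200 - 75):(1200 + 75) + 1L] <- scheme[["FB"]]
  expect_identical(y2, as.integer(brute))

  # unmapped symbol errors and names the symbol
  rec3 <- ecg_record(numeric(n), fs = 250,
                     beat_labels = data.frame(index = 10L, cls = "Z"))
  expect_error(expand_labels(rec3), "Z")

  # determinism
  expect_identical(expand_labels(rec2), expand_labels(rec2))
})

test_that("window dataset cache round-trips through plain text", {
  ds <- make_training_set(8, c(background = .5, VEB = .5), seed = 2,
                          class_scheme = scheme4)
  dir <- withr::local_tempdir()
  write_window_dataset(ds, dir)
  back <- read_window_dataset(dir)
  expect_equal(back$x, ds$x, tolerance = 1e-6)
  expect_identical(back$y, ds$y)
  expect_equal(back$fs, 250)
  expect_identical(back$group, ds$group)
})
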