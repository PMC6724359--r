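test_that("QRS detector finds every beat of a clean 60 bpm record", {
  rec <- clean60()
  b <- detect_qrs(rec)
  m <- match_beats(b$index, rec$beat_labels$index, tol = 10)
  expect_identical(m$fp, 0L)
  expect_identical(m$fn, 0L)
  # R-peaks land exactly on the construction indices
  expect_true(all(abs(b$index - rec$beat_labels$index) <= 2))
})

test_that("flatline input yields an empty beat list with a warning", {
  rec <- ecg_record(numeric(5000), fs = 250)
  expect_warning(b <- detect_qrs(rec), "flatline")
  expect_identical(nrow(b), 0L)
  expect_error(detect_qrs(ecg_record(numeric(100), fs = 250)), "2 s")
})

test_that("detector keeps sensitivity under additive noise", {
  hits <- vapply(1:5, function(s) {
    cfg <- ecg_synth_config(hr_bpm = 75, duration_s = 60, noise_sd = 0.08,
                            seed = 500L + s)
    rec <- synth_ecg(cfg)
    b <- detect_qrs(rec)
    m <- match_beats(b$index, rec$beat_labels$index)
    c(m$tp / (m$tp + m$fn), m$tp / (m$tp + m$fp))
  }, c(0, 0))
  expect_gte(min(hits[1, ]), 0.99)    # sensitivity
  expect_gte(min(hits[2, ]), 0.99)    # positive predictive value
})

test_that("detection is shift-equivariant on interior beats", {
  rec <- clean60()
  k <- 37L
  shifted <- ecg_record(c(rec$samples[(k + 1):length(rec$samples)],
                          rec$samples[1:k]), fs = rec$fs)
  b0 <- detect_qrs(rec)$index
  b1 <- detect_qrs(shifted)$index
  core0 <- b0[b0 > 500 & b0 < 13500]
  core1 <- b1[b1 > 500 - k & b1 < 13500 - k]
  expect_identical(core1, core0 - k)
})

test_that("HR is exact for metronomic beats and tracks alternation", {
  beats <- data.frame(index = seq(0, 59) * 250L,
                      time_s = seq(0, 59), amp = 1)
  hr <- estimate_hr(beats)
  expect_true(all(abs(hr$hr - 60) < 1e-6))

  # alternating 0.5 / 1.0 s intervals: curve passes through 120 and 60
  tb <- cumsum(c(0, rep(c(0.5, 1.0), 20)))
  beats2 <- data.frame(index = as.integer(tb * 250), time_s = tb, amp = 1)
  hr2 <- estimate_hr(beats2, grid_hz = 8)
  mids_fast <- tb[-length(tb)][diff(tb) == 0.5] + 0.25
  mids_slow <- tb[-length(tb)][diff(tb) == 1.0] + 0.5
  at <- function(series, t0) series$hr[which.min(abs(series$t - t0))]
  expect_lt(abs(at(hr2, mids_fast[5]) - 120), 1)
  expect_lt(abs(at(hr2, mids_slow[5]) - 60), 1)

  expect_error(estimate_hr(beats[1:2, ]), "insufficient")
})

test_that("HR tracks a 60-to-120 bpm ramp within 2 bpm", {
  # construct beats directly from the ramp's integrated rate
  t <- 0; tb <- 0
  while (tail(tb, 1) < 60) {
    hr_now <- 60 + tail(tb, 1)  # 60 bpm at t=0 rising 1 bpm/s
    tb <- c(tb, tail(tb, 1) + 60 / hr_now)
  }
  beats <- data.frame(index = as.integer(tb * 250), time_s = tb, amp = 1)
  hr <- estimate_hr(beats)
  truth <- 60 + hr$t
  core <- hr$t > 2 & hr$t < 55
  expect_lt(max(abs(hr$hr - truth)[core]), 2)
})

test_that("vitals are invariant to a constant baseline offset", {
  rec <- clean60()
  off <- ecg_record(rec$samples + 0.7, fs = rec$fs)
  expect_identical(detect_qrs(off)$index, detect_qrs(rec)$index)
  s0 <- snr(rec); s1 <- snr(off)
  expect_equal(s1$mean_db, s0$mean_db, tolerance = 1e-9)
})

test_that("RR recovery is within 1 brpm at moderate modulation", {
  rec <- synth_ecg(ecg_synth_config(hr_bpm = 72, rr_brpm = 15,
                                    resp_mod_depth = 0.2, duration_s = 120,
                                    seed = 21))
  beats <- detect_qrs(rec)
  rr <- estimate_rr(rec, beats)
  expect_true(all(abs(rr$rr - 15) <= 1))
})

test_that("absent modulation reports the not-detectable sentinel", {
  rec <- synth_ecg(ecg_synth_config(hr_bpm = 72, resp_mod_depth = 0,
                                    rsa_depth = 0, wander_amp = 0,
                                    noise_sd = 0.02, duration_s = 60,
                                    seed = 22))
  beats <- detect_qrs(rec)
  rr <- estimate_rr(rec, beats)
  expect_true(all(is.na(rr$rr)))
  expect_error(estimate_rr(rec, beats[1:5, ]), "insufficient")
})

test_that("SNR formula and scale invariance are exact", {
  expect_identical(snr_db(10, 1), 20)
  expect_identical(snr_db(1, 1), 0)
  rec <- synth_ecg(ecg_synth_config(duration_s = 32, seed = 31))
  s1 <- snr(rec)
  s2 <- snr(ecg_record(rec$samples * 3.7, fs = rec$fs))
  expect_equal(s2$per_window_db, s1$per_window_db, tolerance = 1e-12)
})

test_that("measured SNR matches the constructed signal/noise ratio", {
  # calibrated construction: sinusoidal baseline wander is the noise floor
  # the median filter isolates; its mean |amplitude| is 2A/pi. The QRS
  # amplitude is the template's peak-to-trough span.
  tmpl <- shemon:::ecg_beat_template("normal")
  tt <- seq(-0.45, 0.55, by = 1 / 2500)
  v <- shemon:::render_beat_template(tmpl, tt)
  a_sig_true <- max(v) - min(v)
  for (wa in c(0.05, 0.1, 0.2)) {
    rec <- synth_ecg(ecg_synth_config(hr_bpm = 72, resp_mod_depth = 0,
                                      rsa_depth = 0, noise_sd = 0.005,
                                      wander_amp = wa, wander_hz = 0.33,
                                      duration_s = 64, seed = 33))
    rep <- snr(rec)
    truth_db <- snr_db(a_sig_true, 2 * wa / pi)
    expect_lt(abs(rep$mean_db - truth_db), 1.5)
  }
})
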