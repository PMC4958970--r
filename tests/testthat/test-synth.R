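test_that("synth_config validates fields by name", {
  expect_error(synth_config(fs = -1), "fs")
  expect_error(synth_config(bruit_band_hz = c(500, 200)), "bruit_band_hz")
  expect_error(synth_config(bruit_band_hz = c(100, 500)), "bruit_band_hz")
  expect_error(synth_config(fs = 800, bruit_band_hz = c(200, 500)),
               "Nyquist")
  expect_error(synth_config(bruit_duty = 1.2), "bruit_duty")
  expect_error(synth_config(s1_amp = 0.9, s2_amp = 0.3), "amplitudes")
  expect_error(synth_config(s1_freq_hz = 500), "s1_freq_hz")
})

test_that("heart-sound impulse train has the configured beat structure", {
  h <- generate_heart_sounds(synth_config(hr_bpm = 75, duration_s = 5))
  expect_identical(h$n_beats, 6L)              # floor(5 * 75 / 60)
  expect_length(h$impulse_times, 6L)
  expect_equal(diff(h$impulse_times), rep(0.8, 5))

  z <- generate_heart_sounds(synth_config(s1_amp = 0, s2_amp = 0))
  expect_true(all(z$signal$samples == 0))
})

test_that("heart trace drives a pulse-train autocorrelation peak at one period", {
  cfg <- synth_config(hr_bpm = 75, fs = 4000, duration_s = 5)
  h <- generate_heart_sounds(cfg)
  cc <- detect_cardiac_cycle(h$signal)
  expect_true(cc$periodicity$valid)
  expect_lt(abs(cc$periodicity$peak_lag - 3200), 40)
})

test_that("heart-sound energy stays in the low-frequency band", {
  cfg <- synth_config(seed = 9)
  h <- generate_heart_sounds(cfg)
  sp <- Mod(fft(h$signal$samples))^2
  f <- (seq_along(sp) - 1) * cfg$fs / length(sp)
  half <- f <= cfg$fs / 2
  expect_lt(sum(sp[half & f > 150]) / sum(sp[half]), 0.01)
})

test_that("bruit bursts are confined, reproducible, and band-limited", {
  cfg <- synth_config(seed = 3)
  h <- generate_heart_sounds(cfg)
  b1 <- generate_bruits(cfg, h$impulse_times)
  b2 <- generate_bruits(cfg, h$impulse_times)
  expect_identical(b1$signal$samples, b2$signal$samples)  # determinism

  z <- generate_bruits(synth_config(bruit_amp = 0), h$impulse_times)
  expect_true(all(z$signal$samples == 0))
  expect_error(generate_bruits(cfg, numeric(0)), "impulse_times")

  # window confinement: zero outside the systolic windows
  fs <- cfg$fs
  outside <- rep(TRUE, length(b1$signal$samples))
  for (w in seq_len(nrow(b1$systole_windows))) {
    i0 <- max(1, round(b1$systole_windows[w, 1] * fs))
    i1 <- min(length(outside), round(b1$systole_windows[w, 2] * fs) + 1)
    outside[i0:i1] <- FALSE
  }
  expect_true(all(b1$signal$samples[outside] == 0))

  # >= 95% of burst spectral energy above 180 Hz, < 5% below 150 Hz
  sp <- Mod(fft(b1$signal$samples))^2
  f <- (seq_along(sp) - 1) * fs / length(sp)
  half <- f <= fs / 2
  expect_gt(sum(sp[half & f > 180]) / sum(sp[half]), 0.95)
  expect_lt(sum(sp[half & f < 150]) / sum(sp[half]), 0.05)
})

test_that("synthesize_case conserves components and catches clipping", {
  case <- synthesize_case(synth_config(seed = 42))
  with(case$truth$components,
       expect_identical(heart + bruit + breath + white,
                        case$signal$samples))
  expect_true(max(abs(case$signal$samples)) <= 1)
  expect_true(all(case$truth$systole_windows[, 2] <=
                    duration(case$signal) + 1e-9))

  pure <- synthesize_case(synth_config(bruit_amp = 0, breath_amp = 0,
                                       white_amp = 0))
  expect_identical(pure$signal$samples, pure$truth$components$heart)

  case2 <- synthesize_case(synth_config(seed = 42))
  expect_identical(case$signal$samples, case2$signal$samples)
})

test_that("aperiodic bruit timing randomizes the burst windows", {
  cfg <- synth_config(seed = 11, bruit_timing = "aperiodic")
  case <- synthesize_case(cfg)
  w <- case$truth$systole_windows
  expect_true(all(w[, 1] >= 0 & w[, 2] <= cfg$duration_s))
  expect_true(all(diff(w[, 1]) >= 0))
  # window lengths equal the systolic duty length
  expect_equal(unname(w[, 2] - w[, 1]),
               rep(cfg$bruit_duty * 60 / cfg$hr_bpm, nrow(w)))
  # starts differ from the cardiac grid
  sys <- synthesize_case(synth_config(seed = 11))$truth$systole_windows
  expect_false(isTRUE(all.equal(w[, 1], sys[, 1])))
})

test_that("bruit SNR is measured in-window and calibrates linearly", {
  cfg <- synth_config(seed = 7, breath_amp = 0.05, white_amp = 0.01)
  snr0 <- bruit_snr_db(synthesize_case(cfg))
  expect_true(is.finite(snr0))
  cal <- calibrate_bruit_amp(cfg, 6)
  expect_s3_class(cal, "synth_config")
  expect_equal(bruit_snr_db(synthesize_case(cal)), 6, tolerance = 1e-6)
  expect_identical(bruit_snr_db(synthesize_case(synth_config(bruit_amp = 0))),
                   -Inf)
})
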