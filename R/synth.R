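#' Configuration of the synthetic carotid-sound generator
#'
#' Describes a simulated neck recording: damped-sinusoid first and second
#' heart sounds (S1/S2) repeating at a fixed heart rate, band-limited bruit
#' bursts gated into each systolic interval, slow amplitude-modulated
#' low-frequency breathing noise, and broadband white noise.  Every
#' component amplitude is the peak absolute amplitude the component
#' contributes, so the sum of all amplitudes bounds the peak of the mixture
#' and must not exceed 1 (the clipping ceiling of normalized PCM audio).
#'
#' @param fs sampling rate, Hz.
#' @param duration_s recording length, seconds.
#' @param hr_bpm true heart rate, beats per minute.
#' @param s1_amp,s2_amp peak amplitudes of the S1 and S2 impulses.
#' @param s1_freq_hz,s2_freq_hz carrier frequencies of the damped
#'   heart-sound oscillations; must lie in the 10--100 Hz band where
#'   transmitted heart sounds live.
#' @param decay_s exponential decay time constant of S1/S2, seconds.
#' @param systole_frac offset of S2 from S1 as a fraction of the cycle.
#' @param bruit_amp peak amplitude of the bruit bursts.
#' @param bruit_band_hz length-2 vector, bruit frequency band in Hz; the
#'   lower edge must be >= 200 (the clinical definition of a bruit band)
#'   and the upper edge below the Nyquist frequency.
#' @param bruit_duty fraction of the cardiac cycle occupied by each
#'   systolic bruit window (0 < duty < 1).
#' @param bruit_onset_frac delay of the bruit window after S1, as a
#'   fraction of the cycle.
#' @param ramp_s rise/fall time of the burst gate (Tukey ramps), seconds.
#' @param bruit_timing `"systolic"` places one burst in every systolic
#'   interval (cardiac-locked, the bruit model); `"aperiodic"` places the
#'   same number and length of bursts at uniform-random times, a negative
#'   control that should fail the periodicity gate.
#' @param breath_amp peak amplitude of the breathing noise (low-pass
#'   filtered below 50 Hz, slowly amplitude modulated).
#' @param breath_mod_hz breathing modulation rate, Hz.
#' @param white_amp peak amplitude of the white noise floor.
#' @param seed integer RNG seed; all stochastic components derive from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(fs = 4000, duration_s = 5, hr_bpm = 75,
                         s1_amp = 0.5, s2_amp = 0.25,
                         s1_freq_hz = 30, s2_freq_hz = 50,
                         decay_s = 0.025, systole_frac = 0.35,
                         bruit_amp = 0.05, bruit_band_hz = c(200, 500),
                         bruit_duty = 0.3, bruit_onset_frac = 0.05,
                         ramp_s = 0.01,
                         bruit_timing = c("systolic", "aperiodic"),
                         breath_amp = 0.1, breath_mod_hz = 0.3,
                         white_amp = 0.02, seed = 1L) {
  bruit_timing <- match.arg(bruit_timing)
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(hr_bpm, "hr_bpm", lower = 0, strict_lower = TRUE)
  for (f in c("s1_amp", "s2_amp", "bruit_amp", "breath_amp", "white_amp"))
    check_scalar(get(f), f, lower = 0)
  if (s1_amp + s2_amp + bruit_amp + breath_amp + white_amp > 1)
    stop_field("amplitudes",
               "component amplitudes sum above 1; reduce them to avoid clipping")
  for (f in c("s1_freq_hz", "s2_freq_hz"))
    check_scalar(get(f), f, lower = 10, upper = 100)
  if (length(bruit_band_hz) != 2L || bruit_band_hz[1] >= bruit_band_hz[2])
    stop_field("bruit_band_hz", "must be an increasing (low, high) pair")
  if (bruit_band_hz[1] < 200)
    stop_field("bruit_band_hz", "lower edge must be >= 200 Hz")
  if (bruit_band_hz[2] >= fs / 2)
    stop_field("bruit_band_hz", "upper edge must be below the Nyquist frequency")
  check_scalar(bruit_duty, "bruit_duty", lower = 0, strict_lower = TRUE)
  if (bruit_duty >= 1) stop_field("bruit_duty", "must be < 1")
  check_scalar(decay_s, "decay_s", lower = 0, strict_lower = TRUE)
  check_scalar(systole_frac, "systole_frac", lower = 0, strict_lower = TRUE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_field("seed", "must be a single integer")
  structure(list(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                 s1_amp = s1_amp, s2_amp = s2_amp,
                 s1_freq_hz = s1_freq_hz, s2_freq_hz = s2_freq_hz,
                 decay_s = decay_s, systole_frac = systole_frac,
                 bruit_amp = bruit_amp, bruit_band_hz = bruit_band_hz,
                 bruit_duty = bruit_duty, bruit_onset_frac = bruit_onset_frac,
                 ramp_s = ramp_s, bruit_timing = bruit_timing,
                 breath_amp = breath_amp,
                 breath_mod_hz = breath_mod_hz, white_amp = white_amp,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# normalize a vector to unit peak (all-zero stays all-zero)
unit_peak <- function(x) {
  m <- max(abs(x))
  if (m > 0) x / m else x
}

#' Generate the transmitted heart-sound trace
#'
#' Emits exponentially damped sinusoid pairs (S1, S2) repeating with period
#' `60 / hr_bpm` seconds; S2 is offset from S1 by `systole_frac` of the
#' cycle.  Only complete cardiac cycles are emitted, so every beat's
#' systolic interval fits inside the recording.
#'
#' @param config a [synth_config()].
#' @return list with `signal` (an `audio_signal`), `impulse_times` (S1
#'   onset times in seconds) and `n_beats`.
#' @examples
#' h <- generate_heart_sounds(synth_config(hr_bpm = 75, duration_s = 5))
#' h$n_beats  # 6 complete cycles
#' @export
generate_heart_sounds <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / config$hr_bpm
  n_beats <- as.integer(floor(config$duration_s / period))
  x <- numeric(n)
  impulse_times <- numeric(0)
  damped <- function(t0, amp, freq) {
    idx <- which(t >= t0 & t < t0 + 12 * config$decay_s)
    if (!length(idx)) return(invisible(NULL))
    tt <- t[idx] - t0
    # smooth attack-decay amplitude envelope (unit peak at tt = decay_s);
    # an abrupt onset would smear broadband energy above the heart band
    env <- (tt / config$decay_s) * exp(1 - tt / config$decay_s)
    x[idx] <<- x[idx] + amp * env * sin(2 * pi * freq * tt)
    invisible(NULL)
  }
  for (k in seq_len(n_beats) - 1) {
    t0 <- k * period
    impulse_times <- c(impulse_times, t0)
    damped(t0, config$s1_amp, config$s1_freq_hz)
    damped(t0 + config$systole_frac * period, config$s2_amp, config$s2_freq_hz)
  }
  list(signal = audio_signal(x, fs, "synthetic heart sounds"),
       impulse_times = impulse_times, n_beats = n_beats)
}

#' Generate systolic bruit bursts
#'
#' Band-limited white noise (4th-order Butterworth band-pass, zero-phase)
#' gated into each systolic interval by a smooth on/off window with 10 ms
#' raised-cosine ramps; exactly zero outside the windows and bit-identical
#' across calls with the same config.
#'
#' @param config a [synth_config()].
#' @param impulse_times S1 onset times in seconds (nonempty).
#' @return list with `signal` (an `audio_signal`) and `systole_windows`
#'   (two-column matrix of window start/end times in seconds).
#' @export
generate_bruits <- function(config, impulse_times) {
  stopifnot(inherits(config, "synth_config"))
  if (!length(impulse_times))
    stop_field("impulse_times", "must be nonempty")
  fs <- config$fs
  n <- round(config$duration_s * fs)
  period <- 60 / config$hr_bpm
  win_len <- config$bruit_duty * period
  if (identical(config$bruit_timing, "aperiodic")) {
    starts <- with_seed(config$seed + 3L,
                        sort(runif(length(impulse_times), 0,
                                   config$duration_s - win_len)))
    windows <- cbind(start = starts, end = starts + win_len)
  } else {
    windows <- cbind(start = impulse_times + config$bruit_onset_frac * period,
                     end = impulse_times +
                       (config$bruit_onset_frac + config$bruit_duty) * period)
  }
  x <- numeric(n)
  if (config$bruit_amp > 0) {
    noise <- with_seed(config$seed, rnorm(n))
    bf <- signal::butter(4, config$bruit_band_hz / (fs / 2), type = "pass")
    band <- signal::filtfilt(bf, noise)
    gate <- numeric(n)
    ramp <- max(1L, round(config$ramp_s * fs))
    for (w in seq_len(nrow(windows))) {
      i0 <- max(1L, round(windows[w, 1] * fs) + 1L)
      i1 <- min(n, round(windows[w, 2] * fs))
      if (i1 <= i0) next
      len <- i1 - i0 + 1L
      g <- rep(1, len)
      r <- min(ramp, len %/% 2L)
      if (r > 0) {
        up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
        g[seq_len(r)] <- up
        g[len - r + seq_len(r)] <- rev(up)
      }
      gate[i0:i1] <- g
    }
    burst <- unit_peak(band * gate) * config$bruit_amp
    x <- burst
  }
  list(signal = audio_signal(x, fs, "synthetic bruits"),
       systole_windows = windows)
}

# low-frequency breathing noise: < 50 Hz coloured noise under a slow
# (breath_mod_hz) amplitude modulation
generate_breath <- function(config) {
  fs <- config$fs
  n <- round(config$duration_s * fs)
  if (config$breath_amp == 0) return(numeric(n))
  noise <- with_seed(config$seed + 1L, rnorm(n))
  lf <- signal::butter(4, min(50, fs / 2 * 0.9) / (fs / 2), type = "low")
  slow <- signal::filtfilt(lf, noise)
  t <- (seq_len(n) - 1) / fs
  am <- 0.55 + 0.45 * sin(2 * pi * config$breath_mod_hz * t)
  unit_peak(slow * am) * config$breath_amp
}

generate_white <- function(config) {
  n <- round(config$duration_s * config$fs)
  if (config$white_amp == 0) return(numeric(n))
  unit_peak(with_seed(config$seed + 2L, rnorm(n))) * config$white_amp
}

#' Synthesize a complete carotid-sound case with ground truth
#'
#' Sums heart sounds, systolic bruit bursts, breathing noise and white
#' noise.  The emitted signal equals the sum of the stored component traces
#' sample for sample, so every downstream stage can be scored against known
#' truth.
#'
#' @param config a [synth_config()].
#' @return list of class `carotid_case_synth` with elements `signal` (an
#'   `audio_signal`), and `truth`: a list holding `hr_bpm`,
#'   `systole_windows`, `impulse_times`, `n_beats` and `components` (heart,
#'   bruit, breath, white traces).
#' @examples
#' case <- synthesize_case(synth_config(seed = 42))
#' range(case$signal$samples)
#' @export
synthesize_case <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  hs <- generate_heart_sounds(config)
  br <- generate_bruits(config, hs$impulse_times)
  breath <- generate_breath(config)
  white <- generate_white(config)
  x <- hs$signal$samples + br$signal$samples + breath + white
  if (max(abs(x)) > 1)
    stop("synthesized mixture would clip: reduce the component amplitudes",
         call. = FALSE)
  structure(list(
    signal = audio_signal(x, config$fs, "synthetic carotid sound"),
    truth = list(hr_bpm = config$hr_bpm,
                 systole_windows = br$systole_windows,
                 impulse_times = hs$impulse_times,
                 n_beats = hs$n_beats,
                 components = list(heart = hs$signal$samples,
                                   bruit = br$signal$samples,
                                   breath = breath, white = white)),
    config = config), class = "carotid_case_synth")
}

#' In-window bruit signal-to-noise ratio of a synthetic case
#'
#' Measures, inside the ground-truth systolic windows, the RMS of the bruit
#' component against the RMS of the summed noise components (breathing +
#' white), in dB.  This is the SNR scale used when grading detection
#' performance.
#'
#' @param case a `carotid_case_synth`.
#' @return SNR in dB (`-Inf` when the case has no bruit energy).
#' @export
bruit_snr_db <- function(case) {
  stopifnot(inherits(case, "carotid_case_synth"))
  fs <- case$signal$fs
  idx <- unlist(lapply(seq_len(nrow(case$truth$systole_windows)), function(w) {
    i0 <- round(case$truth$systole_windows[w, 1] * fs) + 1L
    i1 <- round(case$truth$systole_windows[w, 2] * fs)
    seq.int(max(1L, i0), min(length(case$signal$samples), i1))
  }))
  rms <- function(v) sqrt(mean(v^2))
  s <- rms(case$truth$components$bruit[idx])
  nz <- rms(case$truth$components$breath[idx] + case$truth$components$white[idx])
  if (s == 0) return(-Inf)
  20 * log10(s / nz)
}

#' Scale the bruit amplitude of a config to hit a target in-window SNR
#'
#' The in-window SNR of [synthesize_case()] is proportional to `bruit_amp`,
#' so a single measurement determines the required amplitude.
#'
#' @param config a [synth_config()].
#' @param target_snr_db desired in-window SNR in dB.
#' @return a new `synth_config` with `bruit_amp` rescaled.
#' @export
calibrate_bruit_amp <- function(config, target_snr_db) {
  stopifnot(inherits(config, "synth_config"))
  if (config$bruit_amp <= 0)
    stop_field("bruit_amp", "must be > 0 to calibrate")
  measured <- bruit_snr_db(synthesize_case(config))
  cfg <- unclass(config)
  cfg$bruit_amp <- config$bruit_amp * 10^((target_snr_db - measured) / 20)
  do.call(synth_config, cfg)
}
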