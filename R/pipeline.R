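# The three detection stages (heart rate, rolling-ball-sifted bruits,
# high-pass-filtered bruits) and the case-level decision rules.

invalid_periodicity <- function(fs, min_bpm, max_bpm) {
  structure(list(acf = numeric(0), fs = fs, rate_bpm = NA_real_,
                 peak_lag = NA_integer_, peak_value = NA_real_,
                 valid = FALSE, min_bpm = min_bpm, max_bpm = max_bpm),
            class = "periodicity_result")
}

# autocorrelation lag ceiling for a rate band (one lag of slack for the
# peak's right neighbour)
band_lag_max <- function(fs, min_bpm, n) min(n - 1L, floor(60 * fs / min_bpm) + 2L)

periodicity_of_trace <- function(trace, fs, min_bpm, max_bpm, min_peak) {
  if (length(trace) < 2L || max(trace) - min(trace) == 0)
    return(invalid_periodicity(fs, min_bpm, max_bpm))
  a <- autocorrelate(trace, lag_max = band_lag_max(fs, min_bpm, length(trace)))
  tryCatch(estimate_rate(a, fs, min_bpm, max_bpm, min_peak),
           error = function(e) invalid_periodicity(fs, min_bpm, max_bpm))
}

#' Detect the cardiac cycle and heart rate
#'
#' Rolling-ball envelopes at a 5 Hz cutoff ride over every heart-sound
#' impulse; their difference (upper minus lower) abstracts the cardiac
#' cycle as an impulse-magnitude pulse train whose autocorrelation peak
#' gives the heart rate.
#'
#' @param x an `audio_signal` (or numeric vector with `fs`), >= 2 s long.
#' @param fs sampling rate when `x` is a bare vector.
#' @param cutoff_hz envelope cutoff frequency (default 5 Hz).
#' @param amplitude_scale geometry amplitude rescale (default 50).
#' @param min_bpm,max_bpm,min_peak rate-search band and prominence gate,
#'   passed to [estimate_rate()].
#' @return list of class `cardiac_cycle`: `pulse_train` (numeric),
#'   `envelopes` (an `envelope_pair`), `periodicity`
#'   (a `periodicity_result`, invalid when the envelopes are degenerate or
#'   no prominent band peak exists).
#' @export
detect_cardiac_cycle <- function(x, fs = NULL, cutoff_hz = 5,
                                 amplitude_scale = 50,
                                 min_bpm = 50, max_bpm = 100,
                                 min_peak = 0.1) {
  x <- as_audio(x, fs)
  if (duration(x) < 2)
    stop("need at least 2 s of signal for cardiac-cycle detection",
         call. = FALSE)
  cfg <- envelope_config(x$fs, cutoff_hz, amplitude_scale)
  pair <- rolling_ball_envelopes(x, cfg)
  n <- length(x$samples)
  if (isTRUE(pair$degenerate)) {
    return(structure(list(pulse_train = numeric(n), envelopes = pair,
                          periodicity = invalid_periodicity(x$fs, min_bpm,
                                                            max_bpm),
                          config = cfg), class = "cardiac_cycle"))
  }
  pulse <- pair$upper - pair$lower
  structure(list(pulse_train = pulse, envelopes = pair,
                 periodicity = periodicity_of_trace(pulse, x$fs, min_bpm,
                                                    max_bpm, min_peak),
                 config = cfg), class = "cardiac_cycle")
}

#' Detect bruits by rolling-ball sifting
#'
#' The recording is first reduced to its first intrinsic mode function
#' (classical EMD, [sift_imf1()]) for its sensitivity to faint
#' high-frequency riders; rolling-ball sifting at a 200 Hz cutoff (ball
#' radius 5 samples at 4000 Hz) then isolates the bruit bursts inside
#' merged/inflated candidate segments, and the Hanning-smoothed rectified
#' bruit trace is autocorrelated for its periodicity.
#'
#' @inheritParams detect_cardiac_cycle
#' @param cutoff_hz rolling-ball cutoff for the bruit ball (default 200 Hz).
#' @param window_s Hanning smoothing window, seconds (default 0.05).
#' @return list of class `bruit_detection`: `bruits` (extracted trace),
#'   `segments`, `imf` (the `imf` object), `smoothed`, `periodicity`.
#' @export
detect_bruits_rbs <- function(x, fs = NULL, cutoff_hz = 200,
                              amplitude_scale = 50, window_s = 0.05,
                              min_bpm = 50, max_bpm = 100, min_peak = 0.1) {
  x <- as_audio(x, fs)
  if (duration(x) < 2)
    stop("need at least 2 s of signal for bruit detection", call. = FALSE)
  n <- length(x$samples)
  empty <- function(imf = NULL) {
    structure(list(bruits = numeric(n),
                   segments = matrix(numeric(0), ncol = 2),
                   imf = imf, smoothed = numeric(n),
                   periodicity = invalid_periodicity(x$fs, min_bpm, max_bpm),
                   method = "rbs"), class = "bruit_detection")
  }
  imf <- tryCatch(sift_imf1(x$samples), error = function(e) NULL)
  if (is.null(imf)) return(empty())
  cfg <- envelope_config(x$fs, cutoff_hz, amplitude_scale)
  sets <- alpha_envelope_sets(imf$samples, cfg)
  sets <- merge_inflate_segments(sets)
  if (nrow(sets$segments) == 0L) return(empty(imf))
  pair <- interpolate_envelopes(sets, imf$samples)
  if (isTRUE(pair$degenerate)) return(empty(imf))
  bruits <- extract_highfreq(imf$samples, pair, sets$segments)
  smoothed <- smooth_hanning(bruits, x$fs, window_s = window_s)
  structure(list(bruits = bruits, segments = sets$segments, imf = imf,
                 smoothed = smoothed,
                 periodicity = periodicity_of_trace(smoothed, x$fs, min_bpm,
                                                    max_bpm, min_peak),
                 method = "rbs"), class = "bruit_detection")
}

# zero-phase FIR high-pass: Hamming-windowed design with half-amplitude
# point at the middle of the transition band, order from the standard
# Hamming transition-width rule (even order as fir1's high-pass requires)
hpf_coefficients <- function(fs, stop_hz = 150, pass_hz = 250) {
  width <- pass_hz - stop_hz
  ord <- ceiling(3.3 * fs / width / 2) * 2
  signal::fir1(ord, (stop_hz + pass_hz) / 2 / (fs / 2), type = "high")
}

#' Detect bruits by zero-phase FIR high-pass filtering
#'
#' The conventional comparison detector: a linear-phase FIR high-pass with
#' stopband edge 150 Hz and passband edge 250 Hz (over 40 dB stopband
#' rejection), applied forward-backward for zero phase, followed by the
#' same Hanning-smoothing/autocorrelation periodicity measurement as the
#' rolling-ball path.
#'
#' @inheritParams detect_cardiac_cycle
#' @param stop_hz,pass_hz stopband and passband edge frequencies, Hz.
#' @param window_s Hanning smoothing window, seconds.
#' @return list of class `bruit_detection`: `bruits` (filtered trace),
#'   `smoothed`, `periodicity`.
#' @export
detect_bruits_hpf <- function(x, fs = NULL, stop_hz = 150, pass_hz = 250,
                              window_s = 0.05, min_bpm = 50, max_bpm = 100,
                              min_peak = 0.1) {
  x <- as_audio(x, fs)
  b <- hpf_coefficients(x$fs, stop_hz, pass_hz)
  if (length(x$samples) <= 3 * length(b))
    stop("signal shorter than the high-pass filter transient", call. = FALSE)
  filtered <- as.numeric(signal::filtfilt(b, x$samples))
  smoothed <- smooth_hanning(filtered, x$fs, window_s = window_s)
  structure(list(bruits = filtered,
                 segments = matrix(numeric(0), ncol = 2), imf = NULL,
                 smoothed = smoothed,
                 periodicity = periodicity_of_trace(smoothed, x$fs, min_bpm,
                                                    max_bpm, min_peak),
                 method = "hpf"), class = "bruit_detection")
}

#' Apply the three case-level decision rules
#'
#' Rule one: the heart rate (HR) is detectable -- a valid, prominent
#' autocorrelation peak inside the physiological band.  Rule two:
#' rolling-ball-sifted (RBS) bruits are present and their periodicity
#' agrees with HR.  Rule three: likewise for the high-pass-filtered (HPF)
#' bruits.  Rules two and three presuppose rule one, so both bruit flags
#' are forced negative when HR is undetectable.
#'
#' @param hr a `cardiac_cycle` from [detect_cardiac_cycle()].
#' @param rbs,hpf `bruit_detection` results.
#' @param agree_tol rate-agreement tolerance in beats/min (default 3).
#' @return object of class `carotid_case`: logical `hr_positive`,
#'   `rbs_positive`, `hpf_positive`; rates `hr_bpm`, `rbs_bpm`, `hpf_bpm`
#'   (NA when the stage is invalid); and the per-stage traces.
#' @export
classify_case <- function(hr, rbs, hpf, agree_tol = 3) {
  hr_pos <- isTRUE(hr$periodicity$valid)
  agree <- function(stage) {
    hr_pos && isTRUE(stage$periodicity$valid) &&
      rates_agree(stage$periodicity$rate_bpm, hr$periodicity$rate_bpm,
                  agree_tol)
  }
  structure(list(hr_positive = hr_pos,
                 rbs_positive = agree(rbs),
                 hpf_positive = agree(hpf),
                 hr_bpm = if (hr_pos) hr$periodicity$rate_bpm else NA_real_,
                 rbs_bpm = if (isTRUE(rbs$periodicity$valid))
                   rbs$periodicity$rate_bpm else NA_real_,
                 hpf_bpm = if (isTRUE(hpf$periodicity$valid))
                   hpf$periodicity$rate_bpm else NA_real_,
                 pulse_train = hr$pulse_train, rbs_bruits = rbs$bruits,
                 hpf_bruits = hpf$bruits, agree_tol = agree_tol),
            class = "carotid_case")
}

#' @export
print.carotid_case <- function(x, ...) {
  flag <- function(f) if (f) "(+)" else "(-)"
  cat(sprintf("carotid case: HR %s  RBS %s  HPF %s\n",
              flag(x$hr_positive), flag(x$rbs_positive),
              flag(x$hpf_positive)))
  if (x$hr_positive)
    cat(sprintf("  heart rate %.1f beats/min; RBS %s, HPF %s beats/min\n",
                x$hr_bpm,
                ifelse(is.na(x$rbs_bpm), "-", sprintf("%.1f", x$rbs_bpm)),
                ifelse(is.na(x$hpf_bpm), "-", sprintf("%.1f", x$hpf_bpm))))
  invisible(x)
}

#' Augmented visual inspection of a carotid sound recording
#'
#' The package's top-level fit: runs the three detection stages
#' (heart-rate, rolling-ball-sifted bruits, high-pass-filtered bruits) on
#' one recording, applies the case rules, and returns an inspection object
#' whose `plot()` method draws the five-row inspection figure and whose
#' `print()`/`summary()` report the flags and rates.
#'
#' @param x an `audio_signal` or numeric vector.
#' @param fs sampling rate when `x` is a bare vector.
#' @param start_s,end_s optional analysis segment in seconds.
#' @param hr_band length-2 vector, heart-rate search band in beats/min.
#' @param agree_tol rate-agreement tolerance, beats/min.
#' @param amplitude_scale geometry amplitude rescale.
#' @param min_peak autocorrelation prominence gate.
#' @return object of class `carotid_inspection`: the `carotid_case`, the
#'   three stage results, the analyzed signal, and a `defaults` echo of
#'   every tunable parameter.
#' @examples
#' \donttest{
#' case <- synthesize_case(synth_config(seed = 42))
#' insp <- inspect_carotid(case$signal)
#' insp
#' }
#' @export
inspect_carotid <- function(x, fs = NULL, start_s = NULL, end_s = NULL,
                            hr_band = c(50, 100), agree_tol = 3,
                            amplitude_scale = 50, min_peak = 0.1) {
  x <- as_audio(x, fs)
  if (!is.null(start_s) || !is.null(end_s)) {
    x <- select_segment(x, if (is.null(start_s)) 0 else start_s,
                        if (is.null(end_s)) duration(x) else end_s)
  }
  hr <- detect_cardiac_cycle(x, amplitude_scale = amplitude_scale,
                             min_bpm = hr_band[1], max_bpm = hr_band[2],
                             min_peak = min_peak)
  rbs <- detect_bruits_rbs(x, amplitude_scale = amplitude_scale,
                           min_bpm = hr_band[1], max_bpm = hr_band[2],
                           min_peak = min_peak)
  hpf <- detect_bruits_hpf(x, min_bpm = hr_band[1], max_bpm = hr_band[2],
                           min_peak = min_peak)
  case <- classify_case(hr, rbs, hpf, agree_tol)
  structure(list(case = case, hr = hr, rbs = rbs, hpf = hpf, signal = x,
                 defaults = list(amplitude_scale = amplitude_scale,
                                 hr_cutoff_hz = 5, bruit_cutoff_hz = 200,
                                 hpf_stop_hz = 150, hpf_pass_hz = 250,
                                 hanning_window_s = 0.05,
                                 hr_band = hr_band, agree_tol = agree_tol,
                                 min_peak = min_peak,
                                 magnify_display = 100),
                 version = as.character(utils::packageVersion("ballsift"))),
            class = "carotid_inspection")
}

#' @export
print.carotid_inspection <- function(x, ...) {
  print(x$case)
  invisible(x)
}

#' @export
summary.carotid_inspection <- function(object, ...) {
  print(object$case)
  cat(sprintf("  signal: %d samples @ %g Hz (%.2f s)\n",
              length(object$signal$samples), object$signal$fs,
              duration(object$signal)))
  cat(sprintf("  RBS segments: %d; EMD sifting iterations: %s\n",
              nrow(object$rbs$segments),
              if (is.null(object$rbs$imf)) "-" else
                object$rbs$imf$n_sift_iters))
  invisible(object)
}
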