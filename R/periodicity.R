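#' Normalized autocorrelation
#'
#' Mean-removed, biased-estimator sample autocorrelation normalized by its
#' lag-0 value (so the central peak is exactly 1).  The first prominent
#' off-center peak of this function locates the dominant period of a
#' pulsatile trace.
#'
#' @param x an `audio_signal` or numeric vector (length >= 2, non-constant).
#' @param lag_max maximum lag in samples (default `length(x) - 1`).
#' @return numeric vector of autocorrelation values at lags `0..lag_max`.
#' @examples
#' a <- autocorrelate(rep(c(1, 0, 0, 0), 25))
#' which.max(a[-1])  # lag 4
#' @export
autocorrelate <- function(x, lag_max = NULL) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  n <- length(samples)
  if (n < 2L) stop("autocorrelation needs at least 2 samples", call. = FALSE)
  if (max(samples) - min(samples) == 0)
    stop("autocorrelation undefined for a constant signal (zero variance)",
         call. = FALSE)
  if (is.null(lag_max)) lag_max <- n - 1L
  lag_max <- min(lag_max, n - 1L)
  as.numeric(acf(samples, lag.max = lag_max, type = "correlation",
                 demean = TRUE, plot = FALSE)$acf)
}

#' Smooth a rectified trace with a Hanning window
#'
#' Full-wave rectifies the input (absolute value, the simplest amplitude
#' envelope) and convolves it with a unit-area Hanning window -- by default
#' 0.05 s long -- producing the regular impulsive form whose
#' autocorrelation yields clean periodicity peaks.  Same-length ("same"
#' alignment) output.
#'
#' @param x an `audio_signal` or numeric vector.
#' @param fs sampling rate in Hz (taken from `x` when it is an
#'   `audio_signal`).
#' @param window_s window length in seconds (default 0.05).
#' @param rectify take `abs(x)` first (default TRUE); set FALSE to smooth a
#'   trace that is already an envelope.
#' @return numeric vector, same length as the input.
#' @export
smooth_hanning <- function(x, fs = NULL, window_s = 0.05, rectify = TRUE) {
  if (inherits(x, "audio_signal")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop("`fs` is required for a bare numeric vector")
  n <- length(x)
  L <- round(window_s * fs)
  if (L >= n)
    stop("Hanning window must be shorter than the signal", call. = FALSE)
  if (L < 2L) return(if (rectify) abs(as.numeric(x)) else as.numeric(x))
  w <- as.numeric(signal::hanning(L))
  w <- w / sum(w)
  v <- if (rectify) abs(as.numeric(x)) else as.numeric(x)
  z <- convolve(v, rev(w), type = "open")    # length n + L - 1
  shift <- (L - 1L) %/% 2L
  z[(1L + shift):(n + shift)]
}

#' Estimate a beat rate from a normalized autocorrelation
#'
#' Searches the lag band corresponding to `[min_bpm, max_bpm]` for the
#' highest local maximum of the autocorrelation.  The estimate is valid
#' only when such a peak exists and its height reaches the prominence
#' threshold; pure noise produces no prominent band peak and is reported
#' invalid rather than given a spurious rate.
#'
#' @param acf_vals normalized autocorrelation at lags `0..L` (from
#'   [autocorrelate()]).
#' @param fs sampling rate, Hz.
#' @param min_bpm,max_bpm physiological search band in beats/min (default
#'   50--100; widen for bradycardia).
#' @param min_peak prominence threshold on the peak height (default 0.1).
#' @return object of class `periodicity_result`: `rate_bpm`, `peak_lag`
#'   (samples), `peak_value`, `valid`, `acf`, `fs` and the band.
#' @export
estimate_rate <- function(acf_vals, fs, min_bpm = 50, max_bpm = 100,
                          min_peak = 0.1) {
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (min_bpm <= 0 || max_bpm <= min_bpm)
    stop_field("min_bpm/max_bpm", "need 0 < min_bpm < max_bpm")
  L <- length(acf_vals) - 1L
  lag_lo <- ceiling(60 * fs / max_bpm)
  lag_hi <- floor(60 * fs / min_bpm)
  if (lag_lo > L)
    stop("empty search band: autocorrelation too short for min rate",
         call. = FALSE)
  lag_hi <- min(lag_hi, L)
  res <- structure(list(acf = acf_vals, fs = fs, rate_bpm = NA_real_,
                        peak_lag = NA_integer_, peak_value = NA_real_,
                        valid = FALSE, min_bpm = min_bpm, max_bpm = max_bpm),
                   class = "periodicity_result")
  lags <- lag_lo:lag_hi
  vals <- acf_vals[lags + 1L]
  prev <- acf_vals[lags]                       # value at lag - 1
  nxt <- if (lag_hi < L) acf_vals[lags + 2L]   # value at lag + 1
         else c(acf_vals[head(lags, -1L) + 2L], Inf)  # boundary: not a peak
  is_peak <- vals >= prev & vals >= nxt & (vals > prev | vals > nxt)
  if (!any(is_peak)) return(res)
  best <- which.max(ifelse(is_peak, vals, -Inf))
  res$peak_lag <- lags[best]
  res$peak_value <- vals[best]
  res$rate_bpm <- 60 * fs / res$peak_lag
  res$valid <- res$peak_value >= min_peak
  res
}

#' @export
print.periodicity_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<periodicity> %.1f beats/min (lag %d, peak %.3f, band %g-%g)\n",
                x$rate_bpm, x$peak_lag, x$peak_value, x$min_bpm, x$max_bpm))
  else
    cat(sprintf("<periodicity> no valid peak in band %g-%g beats/min\n",
                x$min_bpm, x$max_bpm))
  invisible(x)
}

#' Do two estimated rates agree?
#'
#' Rates agree when they differ by at most `tol_bpm` beats/min, or when one
#' matches half or double the other within the same tolerance (the
#' harmonic guard: an autocorrelation peak can land on twice or half the
#' fundamental lag).
#'
#' @param rate_a_bpm,rate_b_bpm rates in beats/min (finite, > 0).
#' @param tol_bpm agreement tolerance (default 3, about one lag bin at
#'   physiological rates).
#' @return logical flag.
#' @examples
#' rates_agree(75, 74)
#' rates_agree(75, 40)
#' @export
rates_agree <- function(rate_a_bpm, rate_b_bpm, tol_bpm = 3) {
  for (v in c(rate_a_bpm, rate_b_bpm))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("rates_agree requires two valid positive rates", call. = FALSE)
  abs(rate_a_bpm - rate_b_bpm) <= tol_bpm ||
    abs(rate_a_bpm - 2 * rate_b_bpm) <= tol_bpm ||
    abs(2 * rate_a_bpm - rate_b_bpm) <= tol_bpm
}
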