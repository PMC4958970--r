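#' Strict local extrema with plateau handling
#'
#' Locates strict local maxima and minima of a sampled trace.  A plateau of
#' equal values flanked by strictly lower (higher) neighbours counts as a
#' single maximum (minimum) at its midpoint, ties broken toward the earlier
#' index.  Runs touching the signal boundary are not extrema.
#'
#' @param x numeric vector (or `audio_signal`), length >= 3.
#' @return list with integer vectors `maxima` and `minima` (1-based).
#' @examples
#' local_extrema(c(0, 1, 1, 0))$maxima  # 2
#' @export
local_extrema <- function(x) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  n <- length(samples)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  r <- rle(samples)
  k <- length(r$values)
  if (k < 3L) return(list(maxima = integer(0), minima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- starts + (r$lengths - 1L) %/% 2L
  v <- r$values
  inner <- 2:(k - 1L)
  is_max <- v[inner] > v[inner - 1L] & v[inner] > v[inner + 1L]
  is_min <- v[inner] < v[inner - 1L] & v[inner] < v[inner + 1L]
  list(maxima = mid[inner][is_max], minima = mid[inner][is_min])
}

# natural cubic spline through extrema with two extrema mirrored across
# each boundary (the standard EMD end-effect remedy), evaluated at 1..n
emd_envelope <- function(idx, val, n) {
  m <- length(idx)
  take <- min(2L, m)
  left_i <- 2 - idx[seq_len(take)]            # reflect across sample 1
  left_v <- val[seq_len(take)]
  right_i <- 2 * n - idx[m - seq_len(take) + 1L]  # reflect across sample n
  right_v <- val[m - seq_len(take) + 1L]
  ord_l <- order(left_i)
  ord_r <- order(right_i)
  xs <- c(left_i[ord_l], idx, right_i[ord_r])
  ys <- c(left_v[ord_l], val, right_v[ord_r])
  keep <- !duplicated(xs)
  spline(xs[keep], ys[keep], xout = seq_len(n), method = "natural")$y
}

#' Extract the first intrinsic mode function by classical EMD sifting
#'
#' Repeatedly subtracts the mean of the natural-cubic-spline envelopes
#' through every local maximum and minimum (no ball tangibility criterion)
#' until the Cauchy criterion `SD = sum((h_prev - h)^2) / sum(h_prev^2)`
#' drops below `sd_threshold` or `max_iters` is reached.  The result is the
#' highest-frequency oscillatory mode riding on the signal's local zero;
#' the residual `x - imf` carries everything slower.
#'
#' @param x an `audio_signal` or numeric vector with at least 4 extrema.
#' @param max_iters maximum sifting iterations (default 10).
#' @param sd_threshold Cauchy stopping threshold (default 0.2, the
#'   classical Hilbert-Huang choice).
#' @return object of class `imf`: list with `samples`, `residual`,
#'   `n_sift_iters`, `converged`.
#' @examples
#' t <- seq(0, 1, by = 1 / 4000)
#' imf <- sift_imf1(sin(2 * pi * 300 * t) * 0.1 + sin(2 * pi * 30 * t))
#' @export
sift_imf1 <- function(x, max_iters = 10, sd_threshold = 0.2) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  n <- length(samples)
  ext0 <- local_extrema(samples)
  if (length(ext0$maxima) + length(ext0$minima) < 4L)
    stop("signal too smooth for EMD: fewer than 4 extrema", call. = FALSE)
  h <- samples
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iters)) {
    ext <- local_extrema(h)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    up <- emd_envelope(ext$maxima, h[ext$maxima], n)
    lo <- emd_envelope(ext$minima, h[ext$minima], n)
    h_new <- h - (up + lo) / 2
    sd_crit <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    iters <- it
    if (sd_crit < sd_threshold) { converged <- TRUE; break }
  }
  structure(list(samples = h, residual = samples - h,
                 n_sift_iters = iters, converged = converged),
            class = "imf")
}

#' @export
print.imf <- function(x, ...) {
  cat(sprintf("<imf> %d samples, %d sifting iteration(s), %s\n",
              length(x$samples), x$n_sift_iters,
              if (x$converged) "converged" else "iteration limit reached"))
  invisible(x)
}
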