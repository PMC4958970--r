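#' Rolling-ball radius for a cutoff frequency
#'
#' The ball diameter is matched to the zero-crossing distance of an
#' oscillation at the cutoff frequency, which makes the radius a quarter of
#' `fs / cutoff_hz` sampling points: `r = max(1, round(fs / (4 *
#' cutoff_hz)))`, rounding half away from zero.  Oscillations faster than
#' the cutoff are rolled over by the ball; slower ones are ridden on.
#'
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz; must not exceed Nyquist (`fs/2`).
#' @return ball radius in sampling points (integer-valued, >= 1).
#' @examples
#' radius_from_cutoff(4000, 200)  # 5
#' radius_from_cutoff(4000, 5)    # 200
#' @export
radius_from_cutoff <- function(fs, cutoff_hz) {
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  if (cutoff_hz > fs / 2)
    stop_field("cutoff_hz", "must not exceed the Nyquist frequency fs/2")
  max(1, round_half_away(fs / (4 * cutoff_hz)))
}

#' Rolling-ball envelope configuration
#'
#' Bundles the geometry parameters of the rolling-ball sifting step.  The
#' ball radius derives from the cutoff frequency via [radius_from_cutoff()];
#' amplitudes are multiplied by `amplitude_scale` before any geometry so
#' that unit-normalized audio spans a comparable range to the sample-index
#' axis (default 50, the working value for 4000 Hz recordings).  The
#' segment parameters govern [merge_inflate_segments()]: recovered extrema
#' closer than `spacing_tol` samples chain into one candidate segment,
#' segments closer than `gap_tol` merge, and each final segment is inflated
#' by `pad` samples per side.  All three default to one cutoff half-period
#' (2r, 2r, r).
#'
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz.
#' @param amplitude_scale multiplicative amplitude rescale applied before
#'   the geometry (> 0).
#' @param spacing_tol,gap_tol,pad segmentation constants in samples; see
#'   above for defaults.
#' @return an object of class `envelope_config` with the derived `radius`.
#' @export
envelope_config <- function(fs, cutoff_hz, amplitude_scale = 50,
                            spacing_tol = NULL, gap_tol = NULL, pad = NULL) {
  r <- radius_from_cutoff(fs, cutoff_hz)
  check_scalar(amplitude_scale, "amplitude_scale", lower = 0,
               strict_lower = TRUE)
  structure(list(fs = fs, cutoff_hz = cutoff_hz, radius = r,
                 amplitude_scale = amplitude_scale,
                 spacing_tol = if (is.null(spacing_tol)) 2 * r else spacing_tol,
                 gap_tol = if (is.null(gap_tol)) 2 * r else gap_tol,
                 pad = if (is.null(pad)) r else pad),
            class = "envelope_config")
}

#' Circumradius of a triangle
#'
#' Radius of the unique circle through three distinct points; collinear
#' points return `Inf` (the circle degenerates to a line).
#'
#' @param p1,p2,p3 length-2 numeric vectors (x, y).
#' @return the circumradius, or `Inf` for collinear points.
#' @examples
#' circumradius(c(0, 0), c(1, 0), c(0, 1))  # sqrt(2)/2
#' @export
circumradius <- function(p1, p2, p3) {
  pts <- rbind(p1, p2, p3)
  if (any(duplicated(pts)))
    stop("circumradius requires three distinct points", call. = FALSE)
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  # 2 * signed area via the cross product
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
           (p2[2] - p1[2]) * (p3[1] - p1[1])
  if (abs(cross) < .Machine$double.eps * max(a, b, cc)^2) return(Inf)
  a * b * cc / (2 * abs(cross))
}

# scaled ordinates of a signal under an envelope config
scaled_y <- function(x, config) config$amplitude_scale * x

#' Maximal tangent ball radii at every sample
#'
#' For each sample point `(i, scale * x[i])` computes the supremum of ball
#' radii that can still touch it from above (`rU_max`) and from below
#' (`rL_max`) without enclosing any other sample.  Points exposed on the
#' corresponding side of the convex hull are `+Inf`: a ball of any radius
#' (in the limit, a half plane) touches them.  Radii are located by
#' bisection on the monotone tangibility predicate to relative precision
#' `rel_tol`; finite radii above `r_cap` saturate to `+Inf`, so the cap
#' should stay far above any ball radius in use (the default is).
#'
#' The per-sample cost grows with the tangent radius itself, so this map is
#' intended for analysis and testing at moderate lengths; the envelope
#' pipeline tests tangibility directly at the working radius instead.
#'
#' @param x an `audio_signal` or numeric vector (>= 3 samples).
#' @param config an [envelope_config()].
#' @param r_cap saturation radius, sample units in the scaled plane.
#' @param rel_tol relative bisection tolerance.
#' @return object of class `tangent_radius_map`: list with `rU_max`,
#'   `rL_max` (per-sample, scaled-plane length units) and the config.
#' @export
tangent_radius_map <- function(x, config, r_cap = 1e7, rel_tol = 1e-9) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  if (length(samples) < 3L)
    stop("tangent_radius_map needs at least 3 samples", call. = FALSE)
  y <- scaled_y(samples, config)
  structure(list(rU_max = rb_tangent_radius_above(y, r_cap, rel_tol),
                 rL_max = rb_tangent_radius_above(-y, r_cap, rel_tol),
                 config = config, n = length(samples)),
            class = "tangent_radius_map")
}

#' Brute-force ball-touch oracle
#'
#' Independent reference for the tangibility criterion, by direct search
#' over candidate tangent-disc centres: for each sample, discs through the
#' point with horizontal and vertical tangency directions plus the two
#' discs through the point and every nearby sample, each verified empty by
#' explicit distance checks.  Quadratic per sample, so restricted to short
#' signals; it exists to cross-check the production geometry, not to run
#' the pipeline.
#'
#' @param x an `audio_signal` or numeric vector.
#' @param scale amplitude scale applied before the geometry.
#' @param r ball radius in scaled-plane sample units.
#' @param side `"above"` or `"below"`.
#' @return logical vector: is each sample touchable by an empty ball of
#'   radius `r` on that side?
#' @export
brute_force_touch <- function(x, scale = 1, r, side = c("above", "below")) {
  side <- match.arg(side)
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  n <- length(samples)
  if (n > 500L)
    stop("brute_force_touch is a test oracle; refuse n > 500", call. = FALSE)
  y <- scale * samples
  if (side == "below") y <- -y
  bft_above(y, r)
}

bft_above <- function(y, r) {
  n <- length(y)
  W <- ceiling(2 * r)
  eps <- r * 1e-10
  touched <- logical(n)
  for (i in seq_len(n)) {
    py <- y[i]
    jj <- setdiff(seq.int(max(1L, i - W), min(n, i + W)), i)
    # sweep extremes of single-point tangency plus the vertical direction
    cx <- i + r * c(1, 0, -1)
    cy <- py + r * c(0, 1, 0)
    if (length(jj)) {
      dx <- jj - i
      dy <- y[jj] - py
      d <- sqrt(dx^2 + dy^2)
      keep <- d < 2 * r
      if (any(keep)) {
        dx <- dx[keep]; dy <- dy[keep]; d <- d[keep]
        h <- sqrt(pmax(0, r^2 - (d / 2)^2))
        nx <- -dy / d; ny <- dx / d
        cx <- c(cx, i + dx / 2 + h * nx, i + dx / 2 - h * nx)
        cy <- c(cy, py + dy / 2 + h * ny, py + dy / 2 - h * ny)
      }
    }
    ok <- cy >= py - eps
    cx <- cx[ok]; cy <- cy[ok]
    if (!length(cx)) next
    if (length(jj)) {
      d2min <- rep(Inf, length(cx))
      for (k in seq_along(jj))
        d2min <- pmin(d2min, (cx - jj[k])^2 + (cy - y[jj[k]])^2)
      touched[i] <- any(d2min >= (r - eps)^2)
    } else touched[i] <- TRUE
  }
  touched
}

#' Ball-touched alpha-shape envelope sets
#'
#' Classifies every sample by the tangibility criterion at the configured
#' ball radius: `upper_idx` are the samples an empty ball of radius `r` can
#' touch from above, `lower_idx` from below, and `overlaid_idx` their
#' intersection (regions where upper and lower raw envelopes coincide --
#' typically slow or faint stretches).  Faint-extrema recovery
#' ([recover_faint_extrema()]) is applied, yielding `upper_recovered` /
#' `lower_recovered` knot sets.
#'
#' @param x an `audio_signal` or numeric vector.
#' @param config an [envelope_config()].
#' @param map optional precomputed [tangent_radius_map()]; when supplied
#'   the sets are thresholded from it instead of retested (the two routes
#'   agree away from radius ties).
#' @return object of class `alpha_envelope_sets` with integer index sets
#'   (1-based) and the config.
#' @export
alpha_envelope_sets <- function(x, config, map = NULL) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  if (length(samples) < 3L)
    stop("alpha_envelope_sets needs at least 3 samples", call. = FALSE)
  r <- config$radius
  if (r <= 0) stop_field("radius", "must be > 0")
  if (is.null(map)) {
    y <- scaled_y(samples, config)
    up <- rb_touch_above(y, r)
    lo <- rb_touch_above(-y, r)
  } else {
    up <- map$rU_max >= r
    lo <- map$rL_max >= r
  }
  sets <- structure(list(upper_idx = which(up), lower_idx = which(lo),
                         overlaid_idx = which(up & lo),
                         upper_recovered = integer(0),
                         lower_recovered = integer(0),
                         segments = NULL, config = config,
                         n = length(samples)),
                    class = "alpha_envelope_sets")
  recover_faint_extrema(sets, samples)
}

#' Recover faint-signal extrema inside overlaid regions
#'
#' Plain radius thresholding mislabels faint oscillations: when the
#' amplitude is small the tangent radii on both sides are large, both balls
#' touch every sample, and the envelopes overlay -- losing the extremum
#' structure of faint bruits.  Recovery keeps, as envelope knots, every
#' strict local maximum among the upper-touched samples (including maxima
#' also touched by the lower ball) and every strict local minimum among the
#' lower-touched samples.  Where no region is overlaid this reduces to the
#' extrema of the plain one-sided sets.
#'
#' @param sets an `alpha_envelope_sets` object.
#' @param x the signal the sets were computed from (`audio_signal` or
#'   numeric vector).
#' @return the sets with `upper_recovered` / `lower_recovered` filled.
#' @export
recover_faint_extrema <- function(sets, x) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  ext <- local_extrema(samples)
  sets$upper_recovered <- intersect(ext$maxima, sets$upper_idx)
  sets$lower_recovered <- intersect(ext$minima, sets$lower_idx)
  sets
}

#' Merge and inflate bruit candidate segments
#'
#' Groups the recovered extrema into candidate segments of similar
#' oscillating time scale: consecutive knots (upper and lower pooled)
#' closer than `spacing_tol` samples chain together, chains separated by
#' gaps up to `gap_tol` merge, and each merged segment is inflated by `pad`
#' samples per side.  A chain of a single knot is discarded: an isolated
#' extremum belongs to a slow feature and carries no oscillating time
#' scale.  Knots outside every segment are dropped from the recovered
#' sets, so the subsequent envelopes stay separated over fast oscillation
#' and collapse elsewhere.
#'
#' @param sets an `alpha_envelope_sets` with recovered knots.
#' @param config optional [envelope_config()]; defaults to the one inside
#'   `sets`.
#' @return the sets, with `segments` (two-column matrix of sample index
#'   spans) and segment-filtered recovered knot sets.
#' @export
merge_inflate_segments <- function(sets, config = sets$config) {
  knots <- sort(unique(c(sets$upper_recovered, sets$lower_recovered)))
  if (!length(knots)) {
    sets$segments <- matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
    sets$upper_recovered <- sets$lower_recovered <- integer(0)
    return(sets)
  }
  brk <- which(diff(knots) > config$spacing_tol)
  starts <- knots[c(1L, brk + 1L)]
  ends <- knots[c(brk, length(knots))]
  # a candidate segment needs an oscillating time scale: an isolated
  # extremum (a chain of one knot) is a slow feature, not a bruit
  keep <- ends > starts
  if (!any(keep)) {
    sets$segments <- matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
    sets$upper_recovered <- sets$lower_recovered <- integer(0)
    return(sets)
  }
  starts <- starts[keep]
  ends <- ends[keep]
  # merge chains separated by small gaps
  seg_s <- numeric(0); seg_e <- numeric(0)
  cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] - cur_e <= config$gap_tol) {
      cur_e <- ends[k]
    } else {
      seg_s <- c(seg_s, cur_s); seg_e <- c(seg_e, cur_e)
      cur_s <- starts[k]; cur_e <- ends[k]
    }
  }
  seg_s <- c(seg_s, cur_s); seg_e <- c(seg_e, cur_e)
  # inflate and clip; re-merge any overlap the inflation created
  seg_s <- pmax(1, seg_s - config$pad)
  seg_e <- pmin(sets$n, seg_e + config$pad)
  if (length(seg_s) > 1L) {
    m_s <- seg_s[1]; m_e <- seg_e[1]; out_s <- numeric(0); out_e <- numeric(0)
    for (k in seq_along(seg_s)[-1]) {
      if (seg_s[k] <= m_e + 1) m_e <- max(m_e, seg_e[k])
      else { out_s <- c(out_s, m_s); out_e <- c(out_e, m_e)
             m_s <- seg_s[k]; m_e <- seg_e[k] }
    }
    seg_s <- c(out_s, m_s); seg_e <- c(out_e, m_e)
  }
  segments <- cbind(start = seg_s, end = seg_e)
  inside <- function(idx) {
    keep <- logical(length(idx))
    for (k in seq_len(nrow(segments)))
      keep <- keep | (idx >= segments[k, 1] & idx <= segments[k, 2])
    idx[keep]
  }
  sets$segments <- segments
  sets$upper_recovered <- inside(sets$upper_recovered)
  sets$lower_recovered <- inside(sets$lower_recovered)
  sets
}

#' Interpolate continuous envelopes through the recovered knots
#'
#' Monotone piecewise-cubic (Fritsch-Carlson) interpolation through the
#' upper and lower knot sets, evaluated at every sample; beyond the first
#' and last knot of a side the envelope extends as a constant.  Monotone
#' cubics cannot overshoot between knots, which keeps the envelopes inside
#' the data's local range.  The local zero is the pointwise mean of the two
#' envelopes.
#'
#' @param sets an `alpha_envelope_sets` with recovered knots (optionally
#'   segment-filtered).
#' @param x the signal (`audio_signal` or numeric vector), original
#'   amplitude units.
#' @return object of class `envelope_pair`: `upper`, `lower`, `local_zero`
#'   (per-sample, original units), `knots_upper`, `knots_lower`, and a
#'   `degenerate` flag (TRUE when either side has fewer than 2 knots, in
#'   which case the envelopes are NULL and the caller should treat the
#'   region as having no extractable component).
#' @export
interpolate_envelopes <- function(sets, x) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  ku <- sets$upper_recovered
  kl <- sets$lower_recovered
  if (length(ku) < 2L || length(kl) < 2L) {
    return(structure(list(upper = NULL, lower = NULL, local_zero = NULL,
                          knots_upper = ku, knots_lower = kl,
                          degenerate = TRUE), class = "envelope_pair"))
  }
  interp_side <- function(k) {
    if (length(k) == 2L) {
      # two knots: monotone cubic degenerates to the connecting line
      f <- approxfun(k, samples[k], rule = 2)
    } else {
      g <- splinefun(k, samples[k], method = "monoH.FC")
      f <- function(t) g(pmin(max(k), pmax(min(k), t)))
    }
    f(seq_along(samples))
  }
  upper <- interp_side(ku)
  lower <- interp_side(kl)
  structure(list(upper = upper, lower = lower,
                 local_zero = (upper + lower) / 2,
                 knots_upper = ku, knots_lower = kl,
                 degenerate = FALSE), class = "envelope_pair")
}

#' Extract the high-frequency component riding on the local zero
#'
#' Inside the candidate segments the extracted component is the signal
#' minus the local zero (mean of the upper and lower envelopes); outside
#' every segment it is exactly zero.
#'
#' @param x the signal (`audio_signal` or numeric vector).
#' @param pair an [interpolate_envelopes()] result (non-degenerate).
#' @param segments two-column matrix of sample-index spans, e.g. from
#'   [merge_inflate_segments()]; `NULL` treats the whole signal as one
#'   segment.
#' @return numeric vector: the extracted component, original units.
#' @export
extract_highfreq <- function(x, pair, segments = NULL) {
  samples <- if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
  if (isTRUE(pair$degenerate))
    stop("degenerate envelopes: no extractable component", call. = FALSE)
  if (length(pair$local_zero) != length(samples))
    stop("envelope pair does not cover the signal", call. = FALSE)
  out <- numeric(length(samples))
  if (is.null(segments))
    segments <- cbind(start = 1, end = length(samples))
  for (k in seq_len(nrow(segments))) {
    idx <- seq.int(segments[k, 1], segments[k, 2])
    out[idx] <- samples[idx] - pair$local_zero[idx]
  }
  out
}

#' Rolling-ball envelopes of a signal
#'
#' Convenience composition of the sifting chain: amplitude scaling,
#' tangibility sets at the configured radius, faint-extrema recovery, and
#' monotone-cubic interpolation.  Envelopes are returned in the original
#' (unscaled) amplitude units.  No segment filtering is applied; use
#' [detect_bruits_rbs()] for the segmented bruit-extraction path.
#'
#' @param x an `audio_signal` or numeric vector.
#' @param config an [envelope_config()].
#' @return an `envelope_pair` (possibly degenerate; see
#'   [interpolate_envelopes()]).
#' @examples
#' s <- synthesize_case(synth_config(seed = 1))
#' env <- rolling_ball_envelopes(s$signal, envelope_config(4000, 5))
#' @export
rolling_ball_envelopes <- function(x, config) {
  sets <- alpha_envelope_sets(x, config)
  interpolate_envelopes(sets, x)
}

#' @export
print.alpha_envelope_sets <- function(x, ...) {
  cat(sprintf(paste0("<alpha_envelope_sets> n=%d, r=%g: |upper|=%d, ",
                     "|lower|=%d, |overlaid|=%d, knots %d/%d, segments %s\n"),
              x$n, x$config$radius, length(x$upper_idx), length(x$lower_idx),
              length(x$overlaid_idx), length(x$upper_recovered),
              length(x$lower_recovered),
              if (is.null(x$segments)) "-" else nrow(x$segments)))
  invisible(x)
}
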