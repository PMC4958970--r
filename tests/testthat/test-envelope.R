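test_that("radius_from_cutoff follows the quarter-wavelength rule", {
  expect_identical(radius_from_cutoff(4000, 200), 5)
  expect_identical(radius_from_cutoff(4000, 5), 200)
  expect_identical(radius_from_cutoff(4000, 1000), 1)
  expect_identical(radius_from_cutoff(4000, 2000), 1)  # floor at 1
  expect_error(radius_from_cutoff(4000, 2001), "Nyquist")
  expect_error(radius_from_cutoff(4000, 0), "cutoff_hz")
})

test_that("circumradius handles right, equilateral, and collinear triangles", {
  expect_equal(circumradius(c(0, 0), c(1, 0), c(0, 1)), sqrt(2) / 2)
  eq <- circumradius(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(eq, 1 / sqrt(3))
  expect_identical(circumradius(c(0, 0), c(1, 0), c(2, 0)), Inf)
  expect_error(circumradius(c(0, 0), c(0, 0), c(1, 1)), "distinct")
})

test_that("tangent radii of canonical shapes match hand geometry", {
  cfg <- config_with_radius(5, scale = 1)
  # constant signal: flat curve touchable by any ball from both sides
  m <- tangent_radius_map(rep(1, 10), cfg)
  expect_true(all(is.infinite(m$rU_max)))
  expect_true(all(is.infinite(m$rL_max)))

  # triangular peak (0,1,0): apex is hull-exposed above (any ball),
  # and capped below by the circumradius of the three points (= 1)
  tri <- tangent_radius_map(c(0, 1, 0), cfg)
  expect_identical(tri$rU_max[2], Inf)
  expect_equal(tri$rL_max[2], 1, tolerance = 1e-6)
  expect_equal(tri$rL_max[2],
               circumradius(c(1, 0), c(2, 1), c(3, 0)), tolerance = 1e-6)

  # apex of (0,1,0) is touched from above at r = 0.5: the disc centred
  # at (apex, apex + 0.5) is empty
  expect_true(brute_force_touch(c(0, 1, 0), scale = 1, r = 0.5,
                                side = "above")[2])
  expect_error(brute_force_touch(rnorm(501), scale = 1, r = 2, "above"),
               "n > 500")
})

test_that("thresholded tangent map agrees with direct set computation", {
  x <- random_signal(150, seed = 21)
  cfg <- config_with_radius(5, scale = 1)
  m <- tangent_radius_map(x, cfg)
  direct <- alpha_envelope_sets(x, cfg)
  via_map <- alpha_envelope_sets(x, cfg, map = m)
  expect_identical(direct$upper_idx, via_map$upper_idx)
  expect_identical(direct$lower_idx, via_map$lower_idx)
})

test_that("envelope sets match the brute-force oracle on mixed signals", {
  for (seed in 1:4) {
    x <- random_signal(120, seed = seed)
    for (r in c(2, 5)) {
      cfg <- config_with_radius(r, scale = 1)
      sets <- alpha_envelope_sets(x, cfg)
      expect_same_sets(sets$upper_idx,
                       which(brute_force_touch(x, 1, r, "above")),
                       info = sprintf("seed %d r %d above", seed, r))
      expect_same_sets(sets$lower_idx,
                       which(brute_force_touch(x, 1, r, "below")),
                       info = sprintf("seed %d r %d below", seed, r))
    }
  }
})

test_that("tiny radius touches every sample; sine crests sort by side", {
  x <- random_signal(80, seed = 5)
  cfg <- config_with_radius(0.4, scale = 1)  # below half the unit spacing
  sets <- alpha_envelope_sets(x, cfg)
  expect_identical(sets$upper_idx, seq_along(x))
  expect_identical(sets$lower_idx, seq_along(x))
  expect_identical(sets$overlaid_idx, seq_along(x))

  # strong sine at a moderate radius: crest samples in the upper set only
  t <- seq_len(150)
  s <- 20 * sin(2 * pi * t / 50)
  sets2 <- alpha_envelope_sets(s, config_with_radius(12, scale = 1))
  crests <- local_extrema(s)$maxima
  expect_true(all(crests %in% sets2$upper_idx))
  expect_false(any(crests %in% sets2$lower_idx))
})

test_that("faint extrema are recovered inside overlaid regions", {
  # faint fast sine: post-scale amplitude 0.05 under r = 5 overlays fully
  t <- seq_len(400)
  s <- 0.05 * sin(2 * pi * t / 13)
  cfg <- config_with_radius(5, scale = 1)
  sets <- alpha_envelope_sets(s, cfg)
  ext <- local_extrema(s)
  expect_identical(sets$overlaid_idx, seq_along(s))  # fully overlaid
  expect_same_sets(sets$upper_recovered, ext$maxima)
  expect_same_sets(sets$lower_recovered, ext$minima)

  # strong signal with no overlaid region: recovery is a no-op
  s2 <- 30 * sin(2 * pi * t / 60)
  sets2 <- alpha_envelope_sets(s2, config_with_radius(5, scale = 1))
  expect_length(intersect(sets2$upper_recovered, sets2$lower_recovered), 0)
  expect_same_sets(sets2$upper_recovered,
                   intersect(local_extrema(s2)$maxima, sets2$upper_idx))

  # constant: no strict extrema at all
  sets3 <- alpha_envelope_sets(rep(2, 50), cfg)
  expect_length(sets3$upper_recovered, 0)
  expect_length(sets3$lower_recovered, 0)
})

test_that("segments merge, inflate, and separate distinct bursts", {
  # two fast bursts separated by > 2r of flatness
  n <- 600
  s <- numeric(n)
  t <- seq_len(100)
  burst <- sin(2 * pi * t / 8)
  s[101:200] <- burst
  s[401:500] <- burst
  cfg <- config_with_radius(5, scale = 10)
  sets <- merge_inflate_segments(alpha_envelope_sets(s, cfg))
  expect_identical(nrow(sets$segments), 2L)
  expect_true(sets$segments[1, 1] <= 105 && sets$segments[1, 2] >= 195)
  expect_true(sets$segments[2, 1] <= 405 && sets$segments[2, 2] >= 495)
  mid <- 300
  expect_false(any(sets$segments[, 1] <= mid & sets$segments[, 2] >= mid))

  # continuous fast oscillation: one segment covering nearly everything
  s2 <- sin(2 * pi * seq_len(n) / 8)
  sets2 <- merge_inflate_segments(alpha_envelope_sets(s2, cfg))
  expect_identical(nrow(sets2$segments), 1L)
  expect_gt(diff(sets2$segments[1, ]) / n, 0.95)

  # no recovered extrema -> empty segment list
  sets3 <- merge_inflate_segments(alpha_envelope_sets(rep(0, 50), cfg))
  expect_identical(nrow(sets3$segments), 0L)

  # slow oscillation only: isolated extrema carry no oscillating time
  # scale, so no candidate segments form
  s4 <- 30 * sin(2 * pi * seq_len(600) / 200)
  sets4 <- merge_inflate_segments(alpha_envelope_sets(s4, cfg))
  expect_identical(nrow(sets4$segments), 0L)
})

test_that("interpolated envelopes hit their knots and stay in range", {
  t <- seq_len(2000)
  s <- sin(2 * pi * t / 13)                   # ~154 periods
  cfg <- config_with_radius(5, scale = 50)
  sets <- alpha_envelope_sets(s, cfg)
  pair <- interpolate_envelopes(sets, s)
  expect_false(pair$degenerate)
  expect_equal(pair$upper[pair$knots_upper], s[pair$knots_upper])
  expect_equal(pair$lower[pair$knots_lower], s[pair$knots_lower])
  expect_equal(pair$local_zero, (pair$upper + pair$lower) / 2)
  # upper envelope of a pure sine stays within 1% of the amplitude
  core <- 100:1900
  expect_lt(max(abs(pair$upper[core] - 1)), 0.01)

  # knots on a straight line reproduce the line
  line <- 0.5 * seq_len(20)
  up <- stats::approx(c(3, 9, 15), line[c(3, 9, 15)], xout = 3:15)$y
  f <- stats::splinefun(c(3, 9, 15), line[c(3, 9, 15)], method = "monoH.FC")
  expect_equal(f(3:15), up)

  # fewer than 2 knots on a side -> degenerate flag
  sets0 <- alpha_envelope_sets(rep(1, 60), cfg)
  expect_true(interpolate_envelopes(sets0, rep(1, 60))$degenerate)
})

test_that("extraction subtracts the local zero inside segments only", {
  t <- seq_len(2000)
  s <- sin(2 * pi * t / 13)
  cfg <- config_with_radius(5, scale = 50)
  sets <- merge_inflate_segments(alpha_envelope_sets(s, cfg))
  pair <- interpolate_envelopes(sets, s)
  out <- extract_highfreq(s, pair, sets$segments)
  # fast sine spanning one whole segment: output ~ input
  expect_gt(cor(out, s), 0.99)
  # conservation inside segments
  for (k in seq_len(nrow(sets$segments))) {
    idx <- seq.int(sets$segments[k, 1], sets$segments[k, 2])
    expect_equal(out[idx] + pair$local_zero[idx], s[idx])
  }
  # signal equal to its own local zero extracts to zero
  expect_equal(extract_highfreq(pair$local_zero, pair, sets$segments),
               numeric(length(s)))
  expect_error(extract_highfreq(s, structure(list(degenerate = TRUE),
                                             class = "envelope_pair")),
               "degenerate")
})

test_that("bruit-free heart signal yields almost no extracted bruit", {
  h <- generate_heart_sounds(synth_config(seed = 13))
  det <- detect_bruits_rbs(h$signal)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(det$bruits) / rms(h$signal$samples), 0.05)
})

test_that("rolling_ball_envelopes composes the chain end to end", {
  case <- synthesize_case(synth_config(seed = 2, hr_bpm = 75))
  cfg5 <- envelope_config(4000, 5)
  pair <- rolling_ball_envelopes(case$signal, cfg5)
  expect_false(pair$degenerate)
  # upper >= lower at every knot of either side
  k <- sort(unique(c(pair$knots_upper, pair$knots_lower)))
  expect_true(all(pair$upper[k] >= pair$lower[k]))
  # pulse train periodicity at one cardiac period
  a <- autocorrelate(pair$upper - pair$lower)
  pk <- estimate_rate(a, 4000)
  expect_true(pk$valid)
  expect_lt(abs(pk$peak_lag - 3200), 40)
})
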