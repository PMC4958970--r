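# Shared helpers for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# reproducible random test signal: mixture of smooth tones and noise so
# both gentle and spiky geometry shows up
random_signal <- function(n, seed) {
  set.seed(seed)
  t <- seq_len(n)
  amp <- runif(1, 0.2, 2)
  f1 <- runif(1, 0.002, 0.05)
  f2 <- runif(1, 0.05, 0.4)
  amp * sin(2 * pi * f1 * t) + runif(1, 0, 1) * sin(2 * pi * f2 * t) +
    rnorm(n, sd = runif(1, 0, 0.5))
}

# envelope_config with an explicit radius, bypassing the cutoff formula
config_with_radius <- function(r, scale = 1) {
  cfg <- envelope_config(4000, 200, amplitude_scale = scale)
  cfg$radius <- r
  cfg$spacing_tol <- 2 * r
  cfg$gap_tol <- 2 * r
  cfg$pad <- r
  cfg
}

expect_same_sets <- function(object, expected, info = NULL) {
  expect_identical(as.integer(object), as.integer(expected), info = info)
}
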