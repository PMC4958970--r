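# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# round-half-away-from-zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage
#'
#' Renders a proportion in \[0, 1\] as a percent string rounded half away
#' from zero, the convention used throughout the package's diagnostic
#' reports (e.g. 26/63 prints as "41.3\%").
#'
#' @param p numeric vector of proportions.
#' @param digits decimal places to keep (default 1).
#' @return character vector of formatted percentages.
#' @examples
#' format_percent(26 / 63)
#' @export
format_percent <- function(p, digits = 1) {
  s <- formatC(round_half_away(100 * p, digits), format = "f",
               digits = digits)
  # whole percentages print without the decimal ("90%", not "90.0%")
  paste0(sub("\\.0+$", "", s), "%")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper)
    stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}
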