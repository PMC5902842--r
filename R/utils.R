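# Shared internal helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves always moving up
#' (e.g. 0.05 -> 0.1), the convention used for every reported percentage.
#' Base `round()` rounds half to even, which disagrees on exact halves.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(63.45, 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count as a percentage of a total
#'
#' The report formatter used everywhere a fraction is printed: half-up
#' rounding to one decimal place.
#'
#' @param count numerator.
#' @param total denominator (> 0).
#' @return numeric percentage, one decimal.
#' @export
#' @examples
#' percent_of(3114, 33123)
percent_of <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, 1)
}

# Draw from a deterministic child seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a child seed from a parent seed and a tag, staying under 2^31.
child_seed <- function(seed, tag) {
  (as.numeric(seed) * 1103515245 + tag * 12345) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
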