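#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero rather than to the even digit,
#' so `round_half_away(28.5) == 29` and `round_half_away(26.25, 0) == 26`.
#' Used for expected nominal-association counts in scan reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + sign(x) * 0.5) / m
}

# stop() with a consistent prefix; keeps validation messages greppable
abort_valid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample skewness and excess kurtosis (moment estimators)
moment_skew <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
moment_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^4) / s^4 - 3
}
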