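# Internal helpers shared across modules.

# Round half away from zero (matches the printed-table convention; base
# round() rounds half to even).
.round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Round a glycemic value for display
#'
#' GI, GL and eGL values are reported to the nearest integer with halves
#' rounded away from zero, the convention used in printed food tables.
#' Internally all computations keep full precision.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_glycemic(c(45.14, 43.85, 12.5))
#' @export
round_glycemic <- function(x) {
  stopifnot(is.numeric(x))
  .round_half_away(x)
}

# Draw from Normal(mean, sd) truncated below at `floor` by inverse-CDF
# sampling (deterministic given the RNG stream, no rejection loop).
.rtnorm <- function(n, mean, sd, floor = 0) {
  if (sd <= 0) return(rep(max(mean, floor), n))
  p_lo <- pnorm(floor, mean, sd)
  qnorm(runif(n, p_lo, 1), mean, sd)
}

# Mean and variance of Normal(mean, sd) truncated below at `floor`.
.tnorm_moments <- function(mean, sd, floor = 0) {
  if (sd <= 0) return(c(mean = max(mean, floor), var = 0))
  a <- (floor - mean) / sd
  lambda <- dnorm(a) / (1 - pnorm(a))
  c(mean = mean + sd * lambda,
    var = sd^2 * (1 + a * lambda - lambda^2))
}

.assert_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}
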