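#' Wrap an angle into the interval (-180, 180]
#'
#' Canonical representative used for effective twists of n-start families.
#' Exactly +180 maps to +180 (not -180).
#'
#' @param theta angle(s) in degrees.
#' @return wrapped angle(s) in degrees, in (-180, 180].
#' @export
wrap_angle <- function(theta) {
  w <- theta %% 360
  ifelse(w > 180, w - 360, w)
}

#' Round half away from zero
#'
#' Reporting convention for "subunits in two turns" style numbers
#' (7.0803 -> 7.1, -7.05 -> -7.1), unlike base round()'s banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Run expr with a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

deg2rad <- function(x) x * pi / 180
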