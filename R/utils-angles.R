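#' Angle helpers
#'
#' Internal helpers for circular arithmetic. All user-facing angles in this
#' package are degrees; radians appear only transiently inside computations.
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return angles in degrees on [0, 360).
#' @keywords internal
wrap360 <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  # guard against 360 - eps rounding back to exactly 360
  y[y >= 360] <- 0
  y
}

#' Smallest unsigned angular difference between two angles (degrees, <= 180)
#' @keywords internal
ang_diff <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b)) %% 360
  pmin(d, 360 - d)
}

#' Linear interpolation of a circular tuning curve at an arbitrary angle
#'
#' Interpolates linearly in angle between the two probed directions flanking
#' `at`, with wraparound from the last direction back to the first.
#'
#' @param directions probed directions, degrees, sorted on [0, 360).
#' @param response response at each probed direction.
#' @param at angle (degrees) at which to interpolate.
#' @return interpolated response value.
#' @keywords internal
circ_interp <- function(directions, response, at) {
  at <- wrap360(at)
  n <- length(directions)
  # extend with wraparound point
  d_ext <- c(directions, directions[1] + 360)
  r_ext <- c(response, response[1])
  if (at < directions[1]) at <- at + 360
  i <- findInterval(at, d_ext, rightmost.closed = TRUE)
  i <- max(1L, min(i, n))
  span <- d_ext[i + 1] - d_ext[i]
  w <- (at - d_ext[i]) / span
  (1 - w) * r_ext[i] + w * r_ext[i + 1]
}

#' Derive a child seed from a run seed
#'
#' Deterministic counter scheme used everywhere the package needs several
#' independent streams from one run seed: child k of seed s is
#' `(s * 101 + k * 9973) mod (2^31 - 1)`, kept strictly positive so it is a
#' valid argument to [set.seed()].
#'
#' @param seed integer run seed.
#' @param k non-negative integer counter.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  s <- (as.double(seed) * 101 + as.double(k) * 9973) %% 2147483647
  as.integer(s) + 1L
}
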