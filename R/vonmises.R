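#' Von Mises tuning-curve fit
#'
#' Fits the circular analog of the Gaussian,
#' \deqn{f(x) = a \, \frac{e^{\kappa \cos(x - \mu)}}{2\pi I_0(\kappa)},}
#' to a tuning curve by minimizing the sum of squared residuals. \eqn{\mu}
#' is the curve center, \eqn{1/\kappa} controls the width (a larger
#' \eqn{\kappa} indicates a sharper fit), and \eqn{I_0} is the modified
#' Bessel function of the first kind of order 0. A free amplitude multiplier
#' \eqn{a} is fit jointly, because the Von Mises form is a normalized density
#' while raw tuning curves are not.
#'
#' The fit is deterministic: for each of a fixed grid of starts (the eight
#' probed directions for \eqn{\mu}, \eqn{\kappa \in \{0.5, 2, 8\}}), the
#' amplitude is profiled out in closed form (it enters linearly) and
#' \eqn{(\mu, \log\kappa)} are optimized by Nelder-Mead; the best of all
#' starts is polished and returned.
#'
#' @param resp a [directional_response()] with at least 3 non-zero responses.
#' @return an object of class `von_mises_fit`: list with `mu` (degrees on
#'   \[0, 360)), `kappa` (>= 0), `amplitude`, `sse`, and `fitted` (the fitted
#'   values at the probed directions).
#' @examples
#' y <- von_mises_value(seq(0, 315, by = 45), mu = 90, kappa = 2, amplitude = 30)
#' fit <- fit_von_mises(directional_response(y))
#' c(fit$mu, fit$kappa)
#' @export
fit_von_mises <- function(resp) {
  resp <- as_directional_response(resp)
  y <- resp$response
  if (sum(y > 0) < 3) stop("need at least 3 non-zero responses to fit")
  th <- resp$directions

  # profiled SSE: given (mu, kappa), the least-squares amplitude is
  # <y, b> / <b, b> with b the unit-amplitude Von Mises basis
  profiled <- function(par) {
    mu <- par[1]
    kappa <- exp(par[2])
    if (!is.finite(kappa) || kappa > 700) return(Inf)
    b <- von_mises_value(th, mu, kappa, amplitude = 1)
    bb <- sum(b^2)
    if (bb < 1e-300) return(Inf)
    a <- sum(y * b) / bb
    sum((y - a * b)^2)
  }

  best <- NULL
  for (mu0 in th) {
    for (k0 in c(0.5, 2, 8)) {
      fit <- stats::optim(c(mu0, log(k0)), profiled, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  # polish the winner
  fit <- stats::optim(best$par, profiled, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  if (fit$value > best$value) fit <- best
  if (!is.finite(fit$value)) {
    stop("Von Mises fit failed to converge from any start")
  }
  mu <- wrap360(fit$par[1])
  kappa <- exp(fit$par[2])
  b <- von_mises_value(th, mu, kappa, amplitude = 1)
  a <- sum(y * b) / sum(b^2)
  structure(list(mu = mu, kappa = kappa, amplitude = a,
                 sse = sum((y - a * b)^2), fitted = a * b),
            class = "von_mises_fit")
}

#' Evaluate the (amplitude-scaled) Von Mises curve
#'
#' @param x angles in degrees.
#' @param mu center, degrees.
#' @param kappa width parameter, >= 0; `kappa = 0` gives a constant curve at
#'   `amplitude / (2 pi)`.
#' @param amplitude multiplicative amplitude (default 1).
#' @return curve values at `x`.
#' @export
von_mises_value <- function(x, mu, kappa, amplitude = 1) {
  stopifnot(kappa >= 0)
  # besselI with expon.scaled avoids overflow: exp(k cos d)/I0(k)
  # = exp(k (cos d - 1)) / (I0(k) e^-k)
  amplitude * exp(kappa * (cos(deg2rad(x - mu)) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("<von_mises_fit> mu = %.2f deg, kappa = %.3f, amplitude = %.3f, sse = %.3g\n",
              x$mu, x$kappa, x$amplitude, x$sse))
  invisible(x)
}
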