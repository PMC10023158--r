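#' Empirical sigmoid nonlinearity between rate difference and eye velocity
#'
#' The relationship between the linear (rate-difference) prediction and
#' measured eye velocity is summarized by the four-parameter base-10
#' sigmoid
#' \deqn{v(r) = v_{min} + \frac{v_{max} - v_{min}}
#'       {1 + 10^{(r_{50} - r)\,m}}}
#' where `vmin` and `vmax` are the asymptotic eye velocities, `r50` is the
#' rate difference at the inflection point (where `v = (vmin + vmax) / 2`),
#' and `m` controls the slope.
#'
#' @name sigmoid
NULL

#' Evaluate the sigmoid
#' @param r rate differences (spikes/s).
#' @param params list or named vector with `vmin`, `vmax`, `r50`, `m`.
#' @return eye velocities, same units as `vmin`/`vmax`.
#' @export
sigmoid_value <- function(r, params) {
  p <- as.list(params)
  p$vmin + (p$vmax - p$vmin) / (1 + 10^((p$r50 - r) * p$m))
}

#' Least-squares fit of the sigmoid nonlinearity
#'
#' Deterministic multi-start fit: for each start on a fixed grid (`r50` at
#' the data quantiles 0.25/0.5/0.75, `m` in {0.01, 0.05, 0.2}), `vmin` and
#' `vmax` are profiled out by linear least squares (they enter the model
#' linearly given `r50` and `m`) and the remaining two parameters are
#' optimized by Nelder-Mead; the best start is polished with a full
#' four-parameter BFGS step. The fit is canonicalized to `m > 0` (the
#' parameterization is symmetric under swapping `vmin`/`vmax` and negating
#' `m`).
#'
#' @param r rate differences (abscissa).
#' @param v eye velocities (ordinate).
#' @param add_origin add the point (0, 0) before fitting, as done for the
#'   four drifting-bar conditions (default `FALSE`).
#' @return an object of class `sigmoid_params`: list with `vmin`, `vmax`,
#'   `r50`, `m`, `sse`.
#' @examples
#' p <- list(vmin = -1.69, vmax = 1.82, r50 = 4.93, m = 0.022)
#' r <- seq(-40, 60, by = 5)
#' fit <- fit_sigmoid(r, sigmoid_value(r, p))
#' unlist(fit[c("vmin", "vmax", "r50", "m")])
#' @export
fit_sigmoid <- function(r, v, add_origin = FALSE) {
  if (add_origin) {
    r <- c(r, 0)
    v <- c(v, 0)
  }
  if (length(r) != length(v)) stop("`r` and `v` must have equal length")
  if (length(r) < 4) stop("need at least 4 points to fit 4 parameters")

  profiled <- function(par) {
    r50 <- par[1]
    m <- par[2]
    s <- 1 / (1 + 10^((r50 - r) * m))
    X <- cbind(1 - s, s)
    fit <- tryCatch(stats::lm.fit(X, v), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(Inf)
    sum(fit$residuals^2)
  }
  starts <- expand.grid(r50 = unname(stats::quantile(r, c(0.25, 0.5, 0.75))),
                        m = c(0.01, 0.05, 0.2))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[k, ]), profiled,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # recover the profiled linear parameters at the best (r50, m)
  r50 <- best$par[1]
  m <- best$par[2]
  s <- 1 / (1 + 10^((r50 - r) * m))
  co <- stats::lm.fit(cbind(1 - s, s), v)$coefficients

  # full 4-parameter polish
  full_sse <- function(p) {
    pred <- p[1] + (p[2] - p[1]) / (1 + 10^((p[3] - r) * p[4]))
    sum((v - pred)^2)
  }
  pol <- stats::optim(c(co[1], co[2], r50, m), full_sse, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  p <- pol$par
  if (!is.finite(pol$value)) stop("sigmoid fit failed to converge")
  if (p[4] < 0) p <- c(p[2], p[1], p[3], -p[4]) # canonicalize to m > 0
  structure(list(vmin = unname(p[1]), vmax = unname(p[2]),
                 r50 = unname(p[3]), m = unname(p[4]),
                 sse = pol$value),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_params> vmin = %.3f, vmax = %.3f, r50 = %.3f, m = %.4f (sse = %.3g)\n",
    x$vmin, x$vmax, x$r50, x$m, x$sse))
  invisible(x)
}
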