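#' Population firing rates over an oscillating-grating cycle
#'
#' Generates Superior and Inferior oDSGC population firing rates on the 5 ms
#' analysis grid of an oscillating-grating stimulus. Each population's rate
#' is a half-wave-rectified copy of the stimulus velocity waveform scaled by
#' a population gain: the Superior rate peaks during the superior-motion
#' half-cycle (positive stimulus velocity), the Inferior rate during the
#' inferior half-cycle, emulating the median cycle-aligned responses used
#' for the instantaneous behavioral prediction.
#'
#' @param stim a `stimulus_profile` of kind `"oscillating"`.
#' @param gain_superior,gain_inferior peak firing rate (spikes/s) each
#'   population reaches at peak stimulus speed in its preferred half-cycle.
#'   Superior > Inferior reproduces the superior bias of the integrated
#'   prediction.
#' @param rect_threshold_hz rectification threshold subtracted before
#'   flooring at 0 (spikes/s).
#' @param modulation_depth multiplies the velocity modulation; 0 gives flat
#'   (zero) rates for both populations.
#' @param noise_sd_hz SD of additive Gaussian rate noise (floored at 0).
#' @param seed integer seed.
#' @return a list of class `population_rates`: `time` (s), `superior`,
#'   `inferior` (spikes/s), `dt`, and the generating parameters.
#' @export
make_grating_rates <- function(stim,
                               gain_superior = 20, gain_inferior = 12,
                               rect_threshold_hz = 0,
                               modulation_depth = 1,
                               noise_sd_hz = 0, seed = 1) {
  stopifnot(inherits(stim, "stimulus_profile"))
  if (stim$kind != "oscillating") {
    stop("`stim` must be an oscillating stimulus")
  }
  stopifnot(noise_sd_hz >= 0, gain_superior >= 0, gain_inferior >= 0)
  vmax <- max(abs(stim$velocity))
  m <- if (vmax > 0) modulation_depth * stim$velocity / vmax else
    rep(0, length(stim$velocity))
  set.seed(derive_seed(seed, 2L))
  n <- length(m)
  noise <- function() if (noise_sd_hz > 0) stats::rnorm(n, 0, noise_sd_hz) else 0
  sup <- pmax(0, gain_superior * pmax(0, m) - rect_threshold_hz + noise())
  inf <- pmax(0, gain_inferior * pmax(0, -m) - rect_threshold_hz + noise())
  structure(list(time = stim$time, superior = sup, inferior = inf,
                 dt = stim$params$dt,
                 params = list(gain_superior = gain_superior,
                               gain_inferior = gain_inferior,
                               rect_threshold_hz = rect_threshold_hz,
                               modulation_depth = modulation_depth,
                               noise_sd_hz = noise_sd_hz, seed = seed)),
            class = "population_rates")
}

#' Synthetic eye-position trace with ground-truth saccades
#'
#' Generates a vertical eye-position trace tracking a stimulus with a given
#' slow-phase gain, plus resetting saccades at Poisson times, a constant
#' drift, and white velocity noise. The ground-truth saccade intervals are
#' retained so detection and removal can be scored against them.
#'
#' The slow-phase velocity is `gain * stimulus velocity + drift + noise`.
#' `gain` may be a single value or a named pair `c(superior = , inferior = )`
#' applied during positive / negative stimulus-velocity stages. Saccades are
#' brief (default 30 ms) constant-velocity displacements whose sign opposes
#' the current accumulated eye displacement (resetting fast nystagmus).
#'
#' @param stim a `stimulus_profile`.
#' @param gain slow-phase gain (scalar or `c(superior=, inferior=)`).
#' @param saccade_rate_hz mean saccade rate (Poisson; 0 disables).
#' @param saccade_amp_deg saccade amplitude in degrees.
#' @param saccade_dur_s saccade duration in seconds.
#' @param drift_deg_s constant drift velocity (positive = superior).
#' @param noise_sd_deg_s SD of white velocity noise, degrees/s.
#' @param seed integer seed.
#' @return an object of class `eye_trace`: `time` (s), `theta` (deg),
#'   `saccades` (data.frame `start`, `end`, `direction`), `dt`, `params`.
#' @export
make_eye_trace <- function(stim, gain = 0.6,
                           saccade_rate_hz = 0.25, saccade_amp_deg = 5,
                           saccade_dur_s = 0.03,
                           drift_deg_s = 0, noise_sd_deg_s = 0, seed = 1) {
  stopifnot(inherits(stim, "stimulus_profile"))
  if (noise_sd_deg_s < 0) stop("`noise_sd_deg_s` must be non-negative")
  dt <- stim$params$dt
  n <- length(stim$time)
  if (length(gain) == 1L) gain <- c(superior = unname(gain), inferior = unname(gain))
  g <- ifelse(stim$velocity >= 0, gain[["superior"]], gain[["inferior"]])

  set.seed(derive_seed(seed, 3L))
  vel <- g * stim$velocity + drift_deg_s
  if (noise_sd_deg_s > 0) vel <- vel + stats::rnorm(n, 0, noise_sd_deg_s)

  saccades <- data.frame(start = numeric(0), end = numeric(0),
                         direction = character(0), stringsAsFactors = FALSE)
  if (saccade_rate_hz > 0) {
    tt <- cumsum(stats::rexp(ceiling(4 * saccade_rate_hz * max(stim$time)) + 8,
                             saccade_rate_hz))
    tt <- tt[tt < max(stim$time) - saccade_dur_s]
    n_samp <- max(1L, round(saccade_dur_s / dt))
    pos_so_far <- cumsum(vel) * dt
    last_end <- -Inf
    for (ts in tt) {
      if (ts - last_end < 2 * saccade_dur_s) next # keep saccades separated
      i0 <- max(2L, round(ts / dt) + 1L)
      i1 <- min(n, i0 + n_samp - 1L)
      # resetting movement: oppose the accumulated displacement
      sgn <- if (pos_so_far[i0] >= 0) -1 else 1
      vel[i0:i1] <- vel[i0:i1] + sgn * saccade_amp_deg / (n_samp * dt)
      pos_so_far <- cumsum(vel) * dt
      saccades <- rbind(saccades, data.frame(
        start = (i0 - 1L) * dt, end = (i1 - 1L) * dt,
        direction = if (sgn > 0) "superior" else "inferior",
        stringsAsFactors = FALSE))
      last_end <- (i1 - 1L) * dt
    }
  }
  theta <- c(0, cumsum(vel[-n]) * dt)
  structure(list(time = stim$time, theta = theta, saccades = saccades,
                 dt = dt,
                 params = list(gain = gain, saccade_rate_hz = saccade_rate_hz,
                               saccade_amp_deg = saccade_amp_deg,
                               saccade_dur_s = saccade_dur_s,
                               drift_deg_s = drift_deg_s,
                               noise_sd_deg_s = noise_sd_deg_s, seed = seed)),
            class = "eye_trace")
}

#' Construct an eye trace from raw samples
#'
#' @param time uniform time grid, seconds.
#' @param theta vertical eye angle, degrees (positive = superior).
#' @param saccades optional data.frame of labeled intervals (`start`, `end`
#'   seconds, `direction`).
#' @return an `eye_trace`.
#' @export
eye_trace <- function(time, theta, saccades = NULL) {
  stopifnot(length(time) == length(theta), length(time) >= 2)
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) stop("time grid must be uniform")
  if (is.null(saccades)) {
    saccades <- data.frame(start = numeric(0), end = numeric(0),
                           direction = character(0), stringsAsFactors = FALSE)
  }
  structure(list(time = time, theta = theta, saccades = saccades,
                 dt = dts[1], params = list()),
            class = "eye_trace")
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %d samples at %g s, %d labeled saccades\n",
              length(x$time), x$dt, nrow(x$saccades)))
  invisible(x)
}
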