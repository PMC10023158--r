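#' Stimulus waveform generation
#'
#' Builds the position/velocity profiles of the visual stimuli used
#' throughout the package: oscillating sinusoidal gratings, unidirectional
#' drifting gratings, and drifting bars.
#'
#' Epoch structure follows the behavioral protocol: an oscillating epoch is
#' 20 s of static grating, 120 s of sinusoidal oscillation (position
#' `A * sin(2 pi t / T)` with phase 0 at moving-phase onset), and 20 s of
#' static grating; a unidirectional epoch is 20 s static, 60 s of constant
#' drift at the given speed, 20 s static. With the default amplitude 20
#' degrees and period 15 s, the 120 s moving phase contains exactly eight
#' complete oscillation cycles. A drifting-bar profile is a single constant-
#' velocity sweep with no static flanks.
#'
#' Velocity is stored as the forward difference of position over each
#' sample step, so the cumulative sum of `velocity * dt` reproduces the
#' position exactly; the final sample's velocity is 0.
#'
#' @param kind `"oscillating"`, `"unidirectional"`, or `"drifting_bar"`.
#' @param amplitude_deg oscillation amplitude in degrees (oscillating kind;
#'   default 20).
#' @param period_s oscillation period in seconds (default 15).
#' @param speed_deg_s drift speed in degrees/second (unidirectional and
#'   drifting-bar kinds; default 10; sign gives direction).
#' @param moving_s duration of the moving phase in seconds (default 120 for
#'   oscillating, 60 for unidirectional and drifting bar).
#' @param flank_s duration of each static flank in seconds (default 20;
#'   forced to 0 for drifting bars).
#' @param spatial_freq_cpd spatial frequency in cycles/degree, carried as
#'   metadata (default 0.15).
#' @param dt sample interval in seconds (default 0.005, the 5 ms analysis
#'   grid).
#' @return an object of class `stimulus_profile`: list with `time`,
#'   `position` (degrees), `velocity` (degrees/s), `kind`, and `params`.
#' @examples
#' s <- make_stimulus("oscillating")
#' n_cycles(s)
#' @export
make_stimulus <- function(kind = c("oscillating", "unidirectional", "drifting_bar"),
                          amplitude_deg = 20, period_s = 15, speed_deg_s = 10,
                          moving_s = NULL, flank_s = 20,
                          spatial_freq_cpd = 0.15, dt = 0.005) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("`dt` must be positive")
  if (kind == "oscillating" && period_s <= 0) stop("`period_s` must be positive")
  if (is.null(moving_s)) moving_s <- if (kind == "oscillating") 120 else 60
  if (kind == "drifting_bar") flank_s <- 0
  total <- 2 * flank_s + moving_s
  n <- round(total / dt)
  t <- seq_len(n + 1L) * dt - dt # 0 .. total
  tm <- t - flank_s              # time since moving-phase onset
  moving <- tm >= 0 & tm <= moving_s

  position <- numeric(n + 1L)
  if (kind == "oscillating") {
    position[moving] <- amplitude_deg * sin(2 * pi * tm[moving] / period_s)
    # flanks hold the boundary positions (0 at onset; end value after)
    after <- tm > moving_s
    position[after] <- amplitude_deg * sin(2 * pi * moving_s / period_s)
  } else {
    position[moving] <- speed_deg_s * tm[moving]
    position[tm > moving_s] <- speed_deg_s * moving_s
  }
  velocity <- c(diff(position) / dt, 0)

  structure(list(
    time = t, position = position, velocity = velocity, kind = kind,
    params = list(amplitude_deg = amplitude_deg, period_s = period_s,
                  speed_deg_s = speed_deg_s, moving_s = moving_s,
                  flank_s = flank_s, spatial_freq_cpd = spatial_freq_cpd,
                  dt = dt)
  ), class = "stimulus_profile")
}

#' Number of complete oscillation cycles in the moving phase
#' @param stim a `stimulus_profile` of kind `"oscillating"`.
#' @return integer count of complete cycles.
#' @export
n_cycles <- function(stim) {
  stopifnot(inherits(stim, "stimulus_profile"), stim$kind == "oscillating")
  floor(stim$params$moving_s / stim$params$period_s + 1e-9)
}

#' Index window of the moving phase
#' @keywords internal
moving_window <- function(stim) {
  tm <- stim$time - stim$params$flank_s
  which(tm >= 0 & tm <= stim$params$moving_s)
}

#' @export
print.stimulus_profile <- function(x, ...) {
  p <- x$params
  cat(sprintf("<stimulus_profile> kind: %s, %.0f s total (%g s flanks), dt = %g s\n",
              x$kind, max(x$time), p$flank_s, p$dt))
  invisible(x)
}
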