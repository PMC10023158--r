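#' Eye-movement kinematics
#'
#' Conversion of tracked pupil landmarks to angular eye position, detection
#' and removal of saccades (fast nystagmus), and slow-phase OKR gain and
#' nystagmus statistics.
#'
#' @name eye_kinematics
NULL

#' Convert pupil displacement to angular eye position
#'
#' Given the horizontal and vertical distances of the pupil from the eye
#' center (camera units) and the radius of rotation between pupil and eye
#' center, the vertical eye angle is `theta = arcsin(dy / rp0)` and the
#' horizontal angle is `phi = arcsin(dx / sqrt(rp0^2 - dy^2))`, both
#' returned in degrees. Positive `dy` corresponds to superior eye position.
#'
#' @param dx,dy pupil-to-eye-center distances, camera units (vectorized).
#' @param rp0 radius of rotation between pupil and eye center (> 0).
#' @return a data.frame with `phi_deg` (horizontal) and `theta_deg`
#'   (vertical).
#' @seealso [project_pupil()] for the inverse (forward) model.
#' @export
pupil_to_angle <- function(dx, dy, rp0) {
  if (any(rp0 <= 0)) stop("`rp0` must be positive")
  if (any(abs(dy) >= rp0)) stop("|dy| >= rp0: outside the eye's rotation range")
  s <- sqrt(rp0^2 - dy^2)
  if (any(abs(dx) >= s)) stop("|dx| >= sqrt(rp0^2 - dy^2): outside the rotation range")
  data.frame(phi_deg = rad2deg(asin(dx / s)),
             theta_deg = rad2deg(asin(dy / rp0)))
}

#' Forward model: project eye angles to pupil displacements
#'
#' Inverse of [pupil_to_angle()]: `dy = rp0 sin(theta)`,
#' `dx = sin(phi) sqrt(rp0^2 - dy^2)`.
#'
#' @param phi_deg,theta_deg horizontal and vertical eye angles, degrees.
#' @param rp0 radius of rotation (> 0).
#' @return a data.frame with `dx` and `dy` in camera units.
#' @export
project_pupil <- function(phi_deg, theta_deg, rp0) {
  if (any(rp0 <= 0)) stop("`rp0` must be positive")
  dy <- rp0 * sin(deg2rad(theta_deg))
  dx <- sin(deg2rad(phi_deg)) * sqrt(rp0^2 - dy^2)
  data.frame(dx = dx, dy = dy)
}

#' Fit the pupil-size to rotation-radius calibration
#'
#' Ordinary least-squares line relating pupil diameter to the radius of
#' rotation `rp0`, as measured by swinging the camera through known angles
#' at several luminances.
#'
#' @param pupil_diameter measured pupil diameters (camera units).
#' @param rp0 measured rotation radii at each diameter.
#' @return an object of class `rp0_model`: list with `slope`, `intercept`,
#'   and `predict(diameter)`.
#' @export
fit_rp0 <- function(pupil_diameter, rp0) {
  if (length(unique(pupil_diameter)) < 2) {
    stop("need at least 2 distinct pupil sizes to fit the calibration")
  }
  fit <- stats::lm(rp0 ~ pupil_diameter)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope, intercept = intercept,
                 predict = function(diameter) intercept + slope * diameter),
            class = "rp0_model")
}

#' Detect saccades from velocity and acceleration thresholds
#'
#' Marks samples whose absolute eye velocity exceeds `vel_thresh` or whose
#' absolute acceleration exceeds `acc_thresh`, merges marked runs separated
#' by less than `min_gap_s`, and labels each interval superior or inferior
#' by the sign of its net displacement.
#'
#' @param trace an [eye_trace()].
#' @param vel_thresh velocity threshold, degrees/s (default 50).
#' @param acc_thresh acceleration threshold, degrees/s^2 (default 2000).
#' @param min_gap_s minimum gap between distinct saccades, s (default 0.05).
#' @param pad_s padding added on each side of a detected interval, s
#'   (default one sample), so that the full displacement is captured.
#' @return a data.frame of intervals: `start`, `end` (seconds), `direction`.
#' @export
detect_saccades <- function(trace, vel_thresh = 50, acc_thresh = 2000,
                            min_gap_s = 0.05, pad_s = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  dt <- trace$dt
  if (is.null(pad_s)) pad_s <- dt
  n <- length(trace$theta)
  vel <- c(diff(trace$theta) / dt, 0)
  acc <- c(0, diff(vel) / dt)
  flagged <- abs(vel) > vel_thresh | abs(acc) > acc_thresh
  if (!any(flagged)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than min_gap_s
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      if ((iv[k, 1] - merged[nrow(merged), 2]) * dt < min_gap_s) {
        merged[nrow(merged), 2] <- iv[k, 2]
      } else {
        merged <- rbind(merged, iv[k, ])
      }
    }
  }
  pad <- max(0L, round(pad_s / dt))
  i0 <- pmax(1L, merged[, 1] - pad)
  i1 <- pmin(n, merged[, 2] + pad)
  disp <- trace$theta[i1] - trace$theta[i0]
  data.frame(start = (i0 - 1L) * dt, end = (i1 - 1L) * dt,
             direction = ifelse(disp >= 0, "superior", "inferior"),
             stringsAsFactors = FALSE)
}

#' Remove saccades from an eye trace
#'
#' Replaces the eye velocity during each saccade interval with its value
#' immediately prior to saccade onset, then reintegrates the velocity from
#' the original starting position to rebuild a desaccaded position trace.
#' An interval starting at the first sample has no pre-onset velocity; 0 is
#' used and the result is flagged.
#'
#' @param trace an [eye_trace()].
#' @param intervals data.frame of saccade intervals (`start`, `end`,
#'   seconds), e.g. from [detect_saccades()]; defaults to the trace's own
#'   labeled saccades.
#' @return an [eye_trace()] with attribute `flagged_start` (logical).
#' @export
remove_saccades <- function(trace, intervals = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  if (is.null(intervals)) intervals <- trace$saccades
  dt <- trace$dt
  n <- length(trace$theta)
  vel <- diff(trace$theta) / dt # vel[i]: velocity over [t_i, t_{i+1})
  flagged <- FALSE
  if (nrow(intervals) > 0) {
    for (k in seq_len(nrow(intervals))) {
      i0 <- max(1L, round(intervals$start[k] / dt) + 1L)
      i1 <- min(n - 1L, round(intervals$end[k] / dt))
      if (i1 < i0) next
      if (i0 == 1L) {
        pre <- 0
        flagged <- TRUE
      } else {
        pre <- vel[i0 - 1L]
      }
      vel[i0:i1] <- pre
    }
  }
  theta <- c(trace$theta[1], trace$theta[1] + cumsum(vel) * dt)
  out <- eye_trace(trace$time, theta)
  attr(out, "flagged_start") <- flagged
  out
}

#' Slow-phase OKR gain per half-oscillation stage
#'
#' For each half-cycle of an oscillating stimulus (superior stage: positive
#' stimulus velocity; inferior stage: negative), the gain is the ratio of
#' mean eye velocity to mean stimulus velocity over the stage. Operates on
#' a desaccaded trace. An alternative regression-slope estimator (eye
#' velocity against stimulus velocity through the origin) is available.
#'
#' @param trace a desaccaded [eye_trace()] time-aligned with `stim`.
#' @param stim a `stimulus_profile` of kind `"oscillating"`.
#' @param estimator `"stage-mean"` (default) or `"slope"`.
#' @return a list with `per_stage` (data.frame: `oscillation`, `stage`,
#'   `gain`) and `median_gain` (named: superior, inferior).
#' @export
slow_phase_gain <- function(trace, stim, estimator = c("stage-mean", "slope")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(trace, "eye_trace"), inherits(stim, "stimulus_profile"))
  if (stim$kind != "oscillating") stop("`stim` must be oscillating")
  if (length(trace$time) != length(stim$time) ||
      max(abs(trace$time - stim$time)) > 1e-9) {
    stop("trace and stimulus grids are misaligned")
  }
  dt <- trace$dt
  eye_vel <- c(diff(trace$theta) / dt, 0)
  P <- stim$params$period_s
  t0 <- stim$params$flank_s
  ncyc <- n_cycles(stim)
  tm <- stim$time - t0

  rows <- list()
  for (cyc in seq_len(ncyc)) {
    for (stage in c("superior", "inferior")) {
      # position A sin(2 pi t / P): velocity positive on the first and last
      # quarter-cycle, negative in between
      if (stage == "superior") {
        idx <- which((tm >= (cyc - 1) * P & tm < (cyc - 1) * P + P / 4) |
                       (tm >= cyc * P - P / 4 & tm < cyc * P))
      } else {
        idx <- which(tm >= (cyc - 1) * P + P / 4 & tm < cyc * P - P / 4)
      }
      sv <- mean(stim$velocity[idx])
      if (abs(sv) < 1e-12) next
      g <- if (estimator == "stage-mean") {
        mean(eye_vel[idx]) / sv
      } else {
        sum(eye_vel[idx] * stim$velocity[idx]) / sum(stim$velocity[idx]^2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        oscillation = cyc, stage = stage, gain = g, stringsAsFactors = FALSE)
    }
  }
  per_stage <- do.call(rbind, rows)
  med <- tapply(per_stage$gain, per_stage$stage, stats::median)
  list(per_stage = per_stage,
       median_gain = c(superior = unname(med[["superior"]]),
                       inferior = unname(med[["inferior"]])))
}

#' Fast- and slow-nystagmus statistics
#'
#' Computes, over the moving phase of the stimulus: the rate of fast
#' nystagmus (saccades) by direction, the cumulative distance traveled
#' during slow nystagmus by stimulus direction (integral of desaccaded
#' velocity), and the baseline drift (median desaccaded eye velocity during
#' the static-grating flanks). Drift subtraction, when requested, is applied
#' to oscillating-grating epochs only: a neutral mean eye position is
#' required for the drift estimate to be meaningful.
#'
#' @param trace an [eye_trace()] (with labeled saccade intervals).
#' @param stim the concurrent `stimulus_profile`.
#' @param intervals saccade intervals; default the trace's labels.
#' @param subtract_drift logical; subtract the estimated drift from the
#'   slow-phase velocity before integrating (oscillating stimuli only).
#' @return list with `fast_rate_hz` (named by direction), `slow_distance_deg`
#'   (net signed slow-phase displacement over the moving phase),
#'   `drift_deg_s`, and `drift_subtracted`.
#' @export
nystagmus_stats <- function(trace, stim, intervals = NULL,
                            subtract_drift = FALSE) {
  stopifnot(inherits(trace, "eye_trace"), inherits(stim, "stimulus_profile"))
  if (is.null(intervals)) intervals <- trace$saccades
  dt <- trace$dt
  mw <- moving_window(stim)
  dur <- length(mw) * dt
  if (dur <= 0) stop("zero-duration moving phase")

  in_moving <- intervals$start >= stim$time[mw[1]] &
    intervals$end <= stim$time[mw[length(mw)]]
  iv <- intervals[in_moving, , drop = FALSE]
  fast_rate <- c(superior = sum(iv$direction == "superior") / dur,
                 inferior = sum(iv$direction == "inferior") / dur)

  des <- remove_saccades(trace, intervals)
  vel <- c(diff(des$theta) / dt, 0)
  flank <- setdiff(seq_along(trace$time), mw)
  drift <- if (length(flank) > 1) stats::median(vel[flank[-length(flank)]]) else NA_real_

  apply_drift <- isTRUE(subtract_drift) && stim$kind == "oscillating" &&
    is.finite(drift)
  v_slow <- vel[mw[-length(mw)]]
  if (apply_drift) v_slow <- v_slow - drift
  slow_distance <- sum(v_slow) * dt

  list(fast_rate_hz = fast_rate, slow_distance_deg = slow_distance,
       drift_deg_s = drift, drift_subtracted = apply_drift)
}
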