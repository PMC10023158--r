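test_that("pupil-to-angle conversion inverts the forward projection", {
  expect_equal(unlist(pupil_to_angle(0, 0, 3)), c(phi_deg = 0, theta_deg = 0))
  # pure horizontal displacement
  a <- pupil_to_angle(3 * sin(pi / 18), 0, 3)
  expect_equal(a$phi_deg, 10, tolerance = 1e-9)
  expect_equal(a$theta_deg, 0)
  # roundtrip on a grid of admissible angles
  grid <- expand.grid(phi = seq(-40, 40, by = 10), theta = seq(-40, 40, by = 10))
  p <- project_pupil(grid$phi, grid$theta, 3.3)
  back <- pupil_to_angle(p$dx, p$dy, 3.3)
  expect_lt(max(abs(back$phi_deg - grid$phi)), 1e-9)
  expect_lt(max(abs(back$theta_deg - grid$theta)), 1e-9)
  expect_error(pupil_to_angle(0, 4, 3), "rotation range")
  expect_error(pupil_to_angle(3, 2.9, 3), "rotation range")
})

test_that("rp0 calibration is an exact least-squares line", {
  m <- fit_rp0(c(1, 2), c(3, 5))
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_equal(m$predict(1.5), 4)
  m2 <- fit_rp0(c(1, 2, 3, 4), rep(3.3, 4))
  expect_equal(m2$slope, 0)
  d <- seq(0.5, 3, by = 0.25)
  m3 <- fit_rp0(d, 1.2 + 0.7 * d)
  expect_equal(m3$slope, 0.7, tolerance = 1e-12)
  expect_equal(m3$intercept, 1.2, tolerance = 1e-12)
  expect_error(fit_rp0(rep(2, 3), 1:3), "distinct")
})

test_that("saccade detection finds inserted saccades with correct signs", {
  stim <- make_stimulus("oscillating")
  tr <- make_eye_trace(stim, gain = 0.6, saccade_rate_hz = 0.2,
                       noise_sd_deg_s = 0, seed = 21)
  iv <- detect_saccades(tr)
  expect_equal(nrow(iv), nrow(tr$saccades))
  # each ground-truth saccade is matched by one detection with the same sign
  for (k in seq_len(nrow(tr$saccades))) {
    hit <- which(iv$start <= tr$saccades$end[k] &
                   iv$end >= tr$saccades$start[k])
    expect_length(hit, 1)
    expect_equal(iv$direction[hit], tr$saccades$direction[k])
  }
  # constant slow drift below threshold: nothing detected
  quiet <- make_eye_trace(stim, gain = 0.5, saccade_rate_hz = 0)
  expect_equal(nrow(detect_saccades(quiet)), 0)
  # thresholds above everything: empty list
  expect_equal(nrow(detect_saccades(tr, vel_thresh = 1e6, acc_thresh = 1e9)), 0)
})

test_that("saccade removal reconstructs the slow component", {
  stim <- make_stimulus("oscillating", moving_s = 30)
  # empty interval list: identity
  tr <- make_eye_trace(stim, gain = 0.5, saccade_rate_hz = 0)
  out <- remove_saccades(tr, tr$saccades)
  expect_equal(out$theta, tr$theta)
  # slow ramp + saccades: desaccaded endpoint near the ramp-only endpoint
  with_sac <- make_eye_trace(stim, gain = 0.5, saccade_rate_hz = 0.3,
                             saccade_amp_deg = 5, seed = 13)
  des <- remove_saccades(with_sac, with_sac$saccades)
  n <- length(tr$theta)
  tol <- nrow(with_sac$saccades) * 0.5 * max(abs(stim$velocity)) * stim$params$dt +
    nrow(with_sac$saccades) * 0.1
  expect_lt(abs(des$theta[n] - tr$theta[n]), max(tol, 0.5))
  # interval starting at sample 0 flags and uses zero velocity
  iv0 <- data.frame(start = 0, end = 0.05, direction = "superior")
  out0 <- remove_saccades(tr, iv0)
  expect_true(attr(out0, "flagged_start"))
})

test_that("slow-phase gain is recovered per stage", {
  stim <- make_stimulus("oscillating")
  # exact tracking: gain 1 in both stages
  perfect <- make_eye_trace(stim, gain = 1, saccade_rate_hz = 0)
  g <- slow_phase_gain(perfect, stim)
  expect_equal(unname(g$median_gain), c(1, 1), tolerance = 1e-9)
  # half-gain tracking
  half <- make_eye_trace(stim, gain = 0.5, saccade_rate_hz = 0)
  g2 <- slow_phase_gain(half, stim)
  expect_equal(unname(g2$median_gain), c(0.5, 0.5), tolerance = 1e-9)
  # asymmetric stage gains recovered after saccade removal
  asym <- make_eye_trace(stim, gain = c(superior = 0.8, inferior = 0.5),
                         saccade_rate_hz = 0.25, noise_sd_deg_s = 0.3,
                         seed = 5)
  des <- remove_saccades(asym, detect_saccades(asym))
  g3 <- slow_phase_gain(des, stim)
  expect_equal(g3$median_gain[["superior"]], 0.8, tolerance = 0.05)
  expect_equal(g3$median_gain[["inferior"]], 0.5, tolerance = 0.05)
  # slope estimator agrees on clean data
  g4 <- slow_phase_gain(half, stim, estimator = "slope")
  expect_equal(unname(g4$median_gain), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(slow_phase_gain(perfect, make_stimulus("unidirectional")),
               "oscillating")
})

test_that("nystagmus statistics count saccades and recover drift", {
  stim <- make_stimulus("oscillating")
  quiet <- make_eye_trace(stim, gain = 0.5, saccade_rate_hz = 0)
  st <- nystagmus_stats(quiet, stim)
  expect_equal(unname(st$fast_rate_hz), c(0, 0))
  # known drift recovered from the static flanks; subtraction nulls it
  drifty <- make_eye_trace(stim, gain = 0.5, saccade_rate_hz = 0,
                           drift_deg_s = -0.3)
  st2 <- nystagmus_stats(drifty, stim)
  expect_equal(st2$drift_deg_s, -0.3, tolerance = 1e-6)
  st3 <- nystagmus_stats(drifty, stim, subtract_drift = TRUE)
  # after subtraction the residual net slow displacement is ~the clean one
  expect_equal(st3$slow_distance_deg, st$slow_distance_deg, tolerance = 1e-3)
  # constant-velocity displacement integrates exactly
  stim2 <- make_stimulus("unidirectional", speed_deg_s = 4, moving_s = 60)
  follow <- make_eye_trace(stim2, gain = 0.5, saccade_rate_hz = 0)
  st4 <- nystagmus_stats(follow, stim2)
  expect_equal(st4$slow_distance_deg, 0.5 * 4 * 60, tolerance = 0.2)
})
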