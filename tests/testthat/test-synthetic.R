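test_that("population generation is reproducible and noise-free when asked", {
  p1 <- make_population(n_superior = 8, n_inferior = 8, seed = 3)
  p2 <- make_population(n_superior = 8, n_inferior = 8, seed = 3)
  expect_identical(p1, p2)
  p3 <- make_population(n_superior = 8, n_inferior = 8, seed = 4)
  expect_false(identical(p1, p3))
  # zero noise + very sharp tuning: responses concentrate at the PD, DSI -> 1
  sharp <- make_population(n_superior = 4, n_inferior = 4,
                           kappa = c(Superior = 60, Inferior = 60),
                           pd_jitter_deg = 0, drive_cv = 0, noise = "none",
                           seed = 1)
  dsis <- vapply(sharp, function(cl) {
    if (all(cl$resp$response == 0)) return(NA_real_)
    direction_selectivity_index(cl$resp)
  }, numeric(1))
  expect_true(all(dsis[!is.na(dsis)] > 0.95))
})

test_that("population medians respect the configured effect structure", {
  # Superior larger and broader; both smaller and sharper at low contrast
  pop <- make_population(seed = 11)
  md <- function(type, contrast, f) {
    stats::median(vapply(pop, function(cl) {
      if (cl$cell_type != type || cl$contrast != contrast) return(NA_real_)
      f(cl$resp)
    }, numeric(1)), na.rm = TRUE)
  }
  area <- function(r) linear_tuning_area(r)
  dsi <- function(r) direction_selectivity_index(r)
  for (ct in c("high", "low")) {
    expect_gt(md("Superior", ct, area), md("Inferior", ct, area))
    expect_lt(md("Superior", ct, dsi), md("Inferior", ct, dsi))
  }
  for (ty in c("Superior", "Inferior")) {
    expect_gt(md(ty, "high", area), md(ty, "low", area))
    expect_lt(md(ty, "high", dsi), md(ty, "low", dsi)) # sharpened at low contrast
  }
})

test_that("effect orderings hold across 100 seeds at default sizes", {
  ok <- vapply(1:100, function(s) {
    pop <- make_population(seed = s)
    type <- vapply(pop, `[[`, "", "cell_type")
    contrast <- vapply(pop, `[[`, "", "contrast")
    # for equally spaced directions the trapezoid area equals the mean
    area <- vapply(pop, function(cl) mean(cl$resp$response), numeric(1))
    dsi <- vapply(pop, function(cl) direction_selectivity_index(cl$resp),
                  numeric(1))
    hi <- contrast == "high"
    sup <- type == "Superior"
    stats::median(area[sup & hi]) > stats::median(area[!sup & hi]) &&
      stats::median(dsi[sup & hi]) < stats::median(dsi[!sup & hi]) &&
      stats::median(area[sup & !hi]) > stats::median(area[!sup & !hi])
  }, logical(1))
  expect_true(all(ok))
})

test_that("synthetic conductance sets honor their configured limits", {
  # untuned inhibition limit: all 8 inhibitory traces identical
  s0 <- make_conductance_set("Superior", kappa_in = 0)
  expect_lt(max(abs(s0$g_in - s0$g_in[, 1])), 1e-12)
  # zero excitatory gain: excitatory trace identically zero
  sz <- make_conductance_set("Superior", g_ex_peak_ns = 0)
  expect_true(all(sz$g_ex == 0))
  expect_error(make_conductance_set("Superior", g_ex_peak_ns = -1))
  # Superior vs Inferior with identical seeds: E/I larger in every direction
  ssup <- make_conductance_set("Superior", seed = 9)
  sinf <- make_conductance_set("Inferior", seed = 9)
  ei_sup <- max(ssup$g_ex) / apply(ssup$g_in, 2, max)
  ei_inf <- max(sinf$g_ex) / apply(sinf$g_in, 2, max)
  expect_true(all(ei_sup > ei_inf))
  # inhibition minimal in the preferred direction, maximal in the null
  peaks <- apply(ssup$g_in, 2, max)
  expect_equal(ssup$directions[which.min(peaks)], 270)
  expect_equal(ssup$directions[which.max(peaks)], 90)
})

test_that("grating rates modulate in antiphase with configurable depth", {
  stim <- make_stimulus("oscillating")
  r <- make_grating_rates(stim, seed = 2)
  mw <- retinokr:::moving_window(stim)
  up <- mw[stim$velocity[mw] > 0]
  down <- mw[stim$velocity[mw] < 0]
  expect_gt(mean(r$superior[up]), mean(r$superior[down]))
  expect_gt(mean(r$inferior[down]), mean(r$inferior[up]))
  expect_true(all(r$superior >= 0) && all(r$inferior >= 0))
  # zero modulation depth: flat rates, flat prediction
  r0 <- make_grating_rates(stim, modulation_depth = 0, seed = 2)
  expect_true(all(r0$superior == 0) && all(r0$inferior == 0))
  p0 <- instantaneous_prediction(r0)
  expect_true(all(p0$position == 0))
  expect_error(make_grating_rates(make_stimulus("unidirectional")),
               "oscillating")
})

test_that("symmetric and asymmetric gains shape the integrated prediction", {
  stim <- make_stimulus("oscillating")
  i_cycle <- which.min(abs(stim$time - (stim$params$flank_s +
                                          stim$params$period_s)))
  # equal gains: position returns to ~0 after one full cycle
  rs <- make_grating_rates(stim, gain_superior = 15, gain_inferior = 15)
  ps <- instantaneous_prediction(rs)
  tol <- 15 * stim$params$dt # one integration step of peak rate
  expect_lt(abs(ps$position[i_cycle]), tol)
  # Superior gain larger: displaced in the superior direction after a cycle
  ra <- make_grating_rates(stim, gain_superior = 20, gain_inferior = 12)
  pa <- instantaneous_prediction(ra)
  expect_gt(pa$position[i_cycle], tol)
})

test_that("synthetic eye traces follow the stimulus exactly when clean", {
  stim <- make_stimulus("oscillating", moving_s = 30)
  tr <- make_eye_trace(stim, gain = 1, saccade_rate_hz = 0,
                       noise_sd_deg_s = 0, drift_deg_s = 0)
  expect_equal(nrow(tr$saccades), 0)
  expect_lt(max(abs(tr$theta - stim$position)), 1e-9)
  expect_error(make_eye_trace(stim, noise_sd_deg_s = -1), "non-negative")
  # reproducibility
  t1 <- make_eye_trace(stim, seed = 8)
  t2 <- make_eye_trace(stim, seed = 8)
  expect_identical(t1, t2)
})
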