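test_that("preferred direction is the vector-sum direction", {
  expect_equal(preferred_direction(dr(c(10, 0, 0, 0, 0, 0, 0, 0))), 0)
  # two equal responses at 0 and 45 bisect
  expect_equal(preferred_direction(dr(c(5, 5, 0, 0, 0, 0, 0, 0))), 22.5)
  # y-components cancel for a symmetric curve
  expect_equal(preferred_direction(dr(c(4, 2, 1, 0, 0, 0, 1, 2))), 0)
  expect_error(preferred_direction(dr(rep(0, 8))), "undefined")
  # balanced opposite responses: zero-magnitude vector sum
  expect_error(preferred_direction(dr(c(3, 0, 0, 0, 3, 0, 0, 0))), "undefined")
})

test_that("DSI matches the definition and its conventions", {
  expect_equal(direction_selectivity_index(dr(rep(5, 8))), 0)
  expect_equal(direction_selectivity_index(dr(c(0, 0, 7, 0, 0, 0, 0, 0))), 1)
  # frozen from the complex-sum oracle: |6.828.| / 10
  expect_equal(direction_selectivity_index(dr(c(4, 2, 1, 0, 0, 0, 1, 2))),
               0.6828427, tolerance = 1e-6)
  # all-zero spike curve -> 1 by convention; non-spike units refuse
  expect_equal(direction_selectivity_index(dr(rep(0, 8))), 1)
  expect_error(direction_selectivity_index(dr(rep(0, 8), unit = "mV")),
               "undefined")
})

test_that("linear tuning-curve area uses the circular trapezoid rule", {
  expect_equal(linear_tuning_area(dr(rep(3, 8))), 3)
  expect_equal(linear_tuning_area(dr(rep(0, 8))), 0) # zero-spike convention
  # delta curve: two 45-degree segments averaging 0.5
  expect_equal(linear_tuning_area(dr(c(1, 0, 0, 0, 0, 0, 0, 0))), 0.125)
  # rectangle alternative shifts delta-like curves
  expect_equal(linear_tuning_area(dr(c(1, 0, 0, 0, 0, 0, 0, 0)),
                                  method = "rectangle"), 0.125)
  expect_error(linear_tuning_area(dr(rep(0, 8), unit = "mV"), "trapezoid"),
               NA) # mV zero curve: plain integral (0), no spike convention
})

test_that("normalization divides by the interpolated PD response", {
  r <- dr(c(4, 2, 1, 0, 0, 0, 1, 2))
  expect_equal(normalize_curve(r)$response,
               c(1, 0.5, 0.25, 0, 0, 0, 0.25, 0.5))
  expect_equal(normalize_curve(dr(rep(2, 8)))$response, rep(1, 8))
  # PD between probed directions: interpolated response used
  r2 <- dr(c(5, 5, 0, 0, 0, 0, 0, 0)) # PD = 22.5, interpolated response 5
  expect_equal(max(normalize_curve(r2)$response), 1)
})

test_that("normalized area is 1 for circular curves, 0 for zero-spike", {
  expect_equal(normalized_area(dr(rep(7, 8))), 1)
  expect_equal(normalized_area(dr(rep(0, 8))), 0)
  # frozen from the trapezoid oracle
  r <- dr(c(4, 2, 1, 0, 0, 0, 1, 2))
  expect_equal(normalized_area(r),
               oracle_trap_area(r$directions, c(1, .5, .25, 0, 0, 0, .25, .5)))
  expect_equal(normalized_area(r), 0.3125)
})

test_that("width at fraction interpolates crossings around the PD", {
  expect_equal(width_at_fraction(dr(c(1, 0, 0, 0, 0, 0, 0, 0)))$width_deg, 45)
  u <- width_at_fraction(dr(rep(4, 8)), 0.5)
  expect_equal(u$width_deg, 360)
  expect_true(u$saturated)
  expect_equal(width_at_fraction(dr(c(4, 2, 1, 0, 0, 0, 1, 2)), 0)$width_deg, 360)
})

test_that("tuning metrics are scale- and rotation-invariant where required", {
  set.seed(42)
  for (k in 1:25) {
    m <- stats::runif(8, 0, 10)
    r <- dr(m)
    # DSI invariant to uniform scaling; area scales linearly
    expect_equal(direction_selectivity_index(dr(3.7 * m)),
                 direction_selectivity_index(r))
    expect_equal(linear_tuning_area(dr(3.7 * m)),
                 3.7 * linear_tuning_area(r))
    # rotating direction labels leaves DSI and normalized area unchanged
    rot <- dr(m[c(3:8, 1:2)])
    expect_equal(direction_selectivity_index(rot),
                 direction_selectivity_index(r), tolerance = 1e-12)
    expect_equal(normalized_area(rot), normalized_area(r), tolerance = 1e-9)
  }
})

test_that("DSI decreases monotonically as tuning width increases", {
  kappas <- c(8, 4, 2, 1, 0.5, 0.25)
  dsis <- vapply(kappas, function(k) {
    direction_selectivity_index(dr(von_mises_value(seq(0, 315, 45), 90, k)))
  }, numeric(1))
  expect_true(all(diff(dsis) < 0))
})

test_that("oDSGC classification applies DSI and axis criteria", {
  # sharply tuned straight-ventral cell -> Superior
  sup <- dr(c(0, 0, 0, 0, 0, 0, 20, 2)) # PD near 270 (ventral)
  expect_equal(classify_odsgc(sup), "Superior")
  inf <- dr(c(0, 0, 20, 2, 0, 0, 0, 0)) # PD near 90 (dorsal)
  expect_equal(classify_odsgc(inf), "Inferior")
  # DSI at 0.04 < 0.05 -> excluded (uniform + small bump)
  weak <- dr(c(10.85, 10, 10, 10, 10, 10, 10, 10))
  expect_lt(direction_selectivity_index(weak), 0.05)
  expect_equal(classify_odsgc(weak), "excluded")
  # strongly tuned but pointing along the temporal-nasal axis -> excluded
  nasal <- dr(c(20, 2, 0, 0, 0, 0, 0, 2)) # PD = 0, on the axis
  expect_equal(classify_odsgc(nasal), "excluded")
  expect_equal(classify_odsgc(dr(rep(0, 8))), "excluded")
})

test_that("Von Mises fit recovers parameters and is equivariant", {
  th <- seq(0, 315, by = 45)
  y <- von_mises_value(th, mu = 90, kappa = 2, amplitude = 30)
  fit <- fit_von_mises(dr(y))
  expect_equal(fit$mu, 90, tolerance = 0.5)
  expect_equal(fit$kappa, 2, tolerance = 0.05)
  expect_lt(fit$sse, 1e-12)
  # rotating the curve by 45 degrees shifts mu by 45, kappa unchanged
  fit2 <- fit_von_mises(dr(y[c(8, 1:7)]))
  expect_equal(fit2$mu, 135, tolerance = 0.5)
  expect_equal(fit2$kappa, fit$kappa, tolerance = 0.01)
  # kappa = 0 gives a constant curve at amplitude / (2 pi)
  expect_equal(von_mises_value(th, 0, 0, amplitude = 2 * pi), rep(1, 8))
  expect_error(fit_von_mises(dr(c(1, 1, 0, 0, 0, 0, 0, 0))), "non-zero")
})

test_that("tuning metrics table summarizes a cell list", {
  cells <- list(a = dr(c(4, 2, 1, 0, 0, 0, 1, 2)), b = dr(rep(0, 8)))
  tab <- tuning_metrics(cells)
  expect_equal(tab$cell_id, c("a", "b"))
  expect_equal(tab$dsi, c(0.6828427, 1), tolerance = 1e-6)
  expect_equal(tab$area[2], 0)
  expect_true(is.na(tab$pd_deg[2]))
})
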