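test_that("Ohm's-law conversion handles signs, flooring, and degenerate holds", {
  expect_equal(current_to_conductance(rep(0, 5), -60, 0)$g_ns, rep(0, 5))
  # -600 pA at a -60 mV driving force is 10 nS
  expect_equal(current_to_conductance(-600, -60, 0)$g_ns, 10)
  res <- current_to_conductance(c(-600, 300), -60, 0)
  expect_equal(res$g_ns, c(10, 0))
  expect_equal(res$n_floored, 1)
  expect_error(current_to_conductance(1, -60, -60), "undefined")
})

test_that("untuned excitation is the pointwise maximum across directions", {
  m <- matrix(stats::runif(80), 10, 8)
  u <- build_untuned_excitation(m)
  expect_true(all(u >= m))
  expect_true(all(apply(m == u, 1, any)))
  same <- matrix(rep(sin(1:10)^2, 8), 10, 8)
  expect_equal(build_untuned_excitation(same), same[, 1])
})

test_that("membrane simulation obeys its limiting cases", {
  set <- make_conductance_set("Superior")
  zero <- conductance_set(set$dt, set$g_in * 0, set$g_ex * 0)
  tr <- simulate_membrane(zero, 0)
  expect_true(all(tr$vm == zero$E_rest_mv))
  expect_equal(tr$n_spikes, 0)
  # constant excitation converges to the two-conductance steady state
  g <- 3
  const <- conductance_set(0.001, matrix(0, 3000, 8), rep(g, 3000),
                           V_thresh_mv = 100)
  trc <- simulate_membrane(const, 0, mode = "subthreshold")
  v_inf <- (g * const$E_ex_mv + const$G_rest_ns * const$E_rest_mv) /
    (g + const$G_rest_ns)
  expect_equal(trc$vm[length(trc$vm)], v_inf, tolerance = 1e-6)
  # threshold above all depolarization: spiking == subthreshold trace
  high <- set
  high$V_thresh_mv <- 100
  a <- simulate_membrane(high, 270, mode = "spiking")
  b <- simulate_membrane(high, 270, mode = "subthreshold")
  expect_equal(a$vm, b$vm)
  expect_equal(a$n_spikes, 0)
  # inhibition and leak only: vm never rises above rest
  inh <- simulate_membrane(set, 90, gain_ex = 0, mode = "subthreshold")
  expect_true(all(inh$vm <= set$E_rest_mv + 1e-12))
  expect_error(simulate_membrane(set, 12.5), "directions")
  expect_error(simulate_membrane(set, 0, dt = 0.002), "refractory")
})

test_that("simulation matches an independent naive Euler integrator", {
  set <- make_conductance_set("Superior", amp_noise_cv = 0.2, seed = 6)
  for (j in c(1, 3, 7)) {
    d <- set$directions[j]
    for (mode in c("spiking", "subthreshold")) {
      tr <- simulate_membrane(set, d, gain_ex = 0.9, gain_in = 1.1,
                              mode = mode)
      or <- oracle_euler(set, j, gain_ex = 0.9, gain_in = 1.1,
                         spiking = mode == "spiking")
      expect_lt(max(abs(tr$vm - or$vm)), 1e-9)
      if (mode == "spiking") expect_equal(tr$n_spikes, or$n_spikes)
    }
  }
})

test_that("halving the integration step barely changes spike counts", {
  set <- make_conductance_set("Superior")
  for (d in set$directions) {
    n1 <- simulate_membrane(set, d, dt = 0.001)$n_spikes
    n2 <- simulate_membrane(set, d, dt = 0.0005)$n_spikes
    expect_lte(abs(n1 - n2), 1)
  }
})

test_that("time-above-threshold proxy is exact and monotone", {
  tr <- structure(list(dt = 0.001, vm = c(-60, -40, -40, -55, -30),
                       spike_times = numeric(0), n_spikes = 0,
                       mode = "subthreshold"), class = "membrane_trace")
  expect_equal(proxy_spike_count(tr, -45), 3 * 0.001)
  expect_equal(proxy_spike_count(tr, -20), 0)
  ths <- seq(-60, -20, by = 5)
  vals <- vapply(ths, function(th) proxy_spike_count(tr, th), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("excitatory gain sweep reproduces the threshold-regime structure", {
  set <- make_conductance_set("Superior")
  sw <- sweep_gain(set, seq(0.1, 2, by = 0.1))
  # zero-gain row: no spikes anywhere, conventions apply
  sw0 <- sweep_gain(set, 0)
  expect_equal(sw0$pd_spikes + sw0$nd_spikes, 0)
  expect_equal(sw0$dsi_spk, 1)
  expect_equal(sw0$norm_area_spk, 0)
  # spike linear tuning area non-decreasing in excitatory gain
  expect_true(all(diff(sw$area_spk) >= 0))
  # a contiguous regime with ND silent but PD spiking exists
  reg <- which(sw$threshold_regime)
  expect_gt(length(reg), 0)
  expect_true(all(diff(reg) == 1))
  expect_error(sweep_gain(set, numeric(0)), "non-empty")
})

test_that("joint-EI gain reduction sharpens spikes but not Vm tuning", {
  set <- make_conductance_set("Superior")
  sj <- sweep_gain(set, c(0.7, 1.3), mode = "joint-EI")
  expect_gt(sj$dsi_spk[1], sj$dsi_spk[2])
  expect_lt(abs(sj$norm_area_vm[1] - sj$norm_area_vm[2]) / sj$norm_area_vm[2],
            0.10)
})

test_that("depolarizing current broadens and hyperpolarizing sharpens spikes", {
  set <- make_conductance_set("Superior")
  i6 <- 6 * set$G_rest_ns # shifts resting vm by ~6 mV
  dep <- retinokr:::model_spike_curve(set, i_inj_pa = i6)
  hyp <- retinokr:::model_spike_curve(set, i_inj_pa = -i6)
  expect_gt(normalized_area(dep), normalized_area(hyp))
  expect_lt(direction_selectivity_index(dep),
            direction_selectivity_index(hyp))
})

test_that("threshold calibration recovers a known threshold", {
  set <- make_conductance_set("Superior")
  truth <- -47.5
  spk <- retinokr:::model_spike_curve(set, v_thresh_mv = truth)
  cal <- calibrate_threshold(set, direction_selectivity_index(spk),
                             normalized_area(spk))
  expect_equal(cal$v_thresh_mv, truth, tolerance = 0.1)
  expect_false(cal$at_boundary)
})

test_that("spike isolation recovers inserted spikes and bridges them", {
  dt <- 1e-4
  t <- seq(0, 2, by = dt)
  smooth <- -55 + 8 * exp(-((t - 1) / 0.3)^2)
  spike_shape <- c(seq(0, 60, length.out = 8), seq(60, -5, length.out = 12),
                   seq(-5, 0, length.out = 6))
  vm <- smooth
  at <- c(0.8, 1.0, 1.2)
  for (ts in at) {
    i <- round(ts / dt) + 1
    vm[i:(i + length(spike_shape) - 1)] <-
      vm[i:(i + length(spike_shape) - 1)] + spike_shape
  }
  res <- isolate_subthreshold(vm, dt)
  expect_equal(length(res$spike_times), 3)
  expect_equal(res$spike_times, at, tolerance = 2 * dt)
  expect_lt(max(abs(res$vm_interp - smooth)), 1.5)
  # no spikes: identity
  clean <- isolate_subthreshold(smooth, dt)
  expect_equal(clean$vm_interp, smooth)
  expect_equal(length(clean$spike_times), 0)
  # two spikes closer than the refractory period merge into one event
  vm2 <- smooth
  for (ts in c(1.0, 1.001)) {
    i <- round(ts / dt) + 1
    vm2[i:(i + length(spike_shape) - 1)] <-
      vm2[i:(i + length(spike_shape) - 1)] + spike_shape
  }
  res2 <- isolate_subthreshold(vm2, dt, min_refractory_s = 0.003)
  expect_equal(length(res2$spike_times), 1)
  expect_error(isolate_subthreshold(c(1, NA, 3), dt), "NA")
})

test_that("Vm tuning curves are deflections from baseline", {
  flat <- lapply(1:8, function(i) rep(-55, 100))
  expect_equal(vm_tuning_curve(flat, -55)$response, rep(0, 8))
  # constant offset of traces and baseline cancels
  tr <- lapply(1:8, function(i) -55 + i * sin(seq(0, pi, length.out = 51)))
  a <- vm_tuning_curve(tr, -55)
  b <- vm_tuning_curve(lapply(tr, function(x) x + 7), -48)
  expect_equal(a$response, b$response)
  expect_equal(a$response, 1:8)
  # pipeline self-consistency with the simulator
  set <- make_conductance_set("Superior")
  sims <- lapply(set$directions, function(d) {
    simulate_membrane(set, d, mode = "subthreshold")$vm
  })
  curve <- vm_tuning_curve(sims, set$E_rest_mv)
  expect_equal(curve$response, retinokr:::model_vm_curve(set)$response)
  expect_error(vm_tuning_curve(sims[1:5], -54), "per direction")
})
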