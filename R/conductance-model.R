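#' Parallel-conductance model of an oDSGC
#'
#' A single-compartment membrane driven by separately specified excitatory,
#' inhibitory, and leak conductances:
#' \deqn{C \frac{dV}{dt} = G_{ex}(E_{ex} - V_m) + G_{in}(E_{in} - V_m) +
#'       G_{rest}(E_{rest} - V_m)}
#' integrated by forward Euler at a 1 ms default step. In spiking mode,
#' whenever the membrane potential surpasses the threshold a spike is
#' counted, integration pauses for the 3 ms spike-plus-refractory window,
#' and the potential is reset to rest. In subthreshold mode no reset occurs
#' and the peak depolarization above rest defines the Vm tuning response.
#'
#' @name conductance_model
NULL

#' Conductance set container
#'
#' @param dt time step of the conductance grid, seconds.
#' @param g_in matrix of inhibitory conductances, nS (time in rows, the 8
#'   directions in columns).
#' @param g_ex single untuned excitatory conductance series, nS.
#' @param directions direction labels, degrees (8 at 45 degree spacing).
#' @param E_ex_mv,E_in_mv,E_rest_mv reversal and rest potentials, mV; must
#'   satisfy `E_in <= E_rest < E_ex`.
#' @param C_pf membrane capacitance, pF (> 0).
#' @param G_rest_ns leak conductance, nS (> 0).
#' @param V_thresh_mv spike threshold, mV.
#' @param t_refr_s spike-plus-refractory pause, seconds (default 3 ms).
#' @param meta free-form metadata list.
#' @return an object of class `conductance_set`.
#' @export
conductance_set <- function(dt, g_in, g_ex, directions = seq(0, 315, by = 45),
                            E_ex_mv = 0, E_in_mv = -60, E_rest_mv = -54,
                            C_pf = 60, G_rest_ns = 6.67,
                            V_thresh_mv = -46.2, t_refr_s = 0.003,
                            meta = list()) {
  g_in <- as.matrix(g_in)
  stopifnot(dt > 0, ncol(g_in) == 8L, length(g_ex) == nrow(g_in),
            length(directions) == 8L, C_pf > 0, G_rest_ns > 0, t_refr_s >= 0)
  if (any(g_in < 0) || any(g_ex < 0)) stop("conductances must be non-negative")
  if (!(E_in_mv <= E_rest_mv && E_rest_mv < E_ex_mv)) {
    stop("potentials must satisfy E_in <= E_rest < E_ex")
  }
  structure(list(dt = dt, time = (seq_len(nrow(g_in)) - 1L) * dt,
                 g_in = g_in, g_ex = as.double(g_ex),
                 directions = as.double(directions),
                 E_ex_mv = E_ex_mv, E_in_mv = E_in_mv, E_rest_mv = E_rest_mv,
                 C_pf = C_pf, G_rest_ns = G_rest_ns,
                 V_thresh_mv = V_thresh_mv, t_refr_s = t_refr_s, meta = meta),
            class = "conductance_set")
}

#' @export
print.conductance_set <- function(x, ...) {
  cat(sprintf(
    "<conductance_set> %d samples at %g ms; peak g_ex %.2f nS, peak g_in %.2f nS\n",
    nrow(x$g_in), x$dt * 1000, max(x$g_ex), max(x$g_in)))
  cat(sprintf("  C = %g pF, G_rest = %g nS, E_rest = %g mV, V_thresh = %g mV\n",
              x$C_pf, x$G_rest_ns, x$E_rest_mv, x$V_thresh_mv))
  invisible(x)
}

#' Convert clamp currents to conductances by Ohm's law
#'
#' `G = I / (V_hold - E_rev)` evaluated after subtracting the liquid
#' junction potential from both the holding potential and the reversal
#' potential (the correction cancels in the difference). With current in pA
#' and potentials in mV the result is in nS. Negative conductances (clamp
#' noise) are floored at 0 and counted.
#'
#' @param i_pa current series, pA.
#' @param v_hold_mv holding potential, mV.
#' @param e_rev_mv reversal potential of the isolated current, mV.
#' @param junction_mv liquid junction potential, mV (default 5).
#' @return list with `g_ns` (non-negative conductance series) and
#'   `n_floored` (count of negative values floored).
#' @export
current_to_conductance <- function(i_pa, v_hold_mv, e_rev_mv, junction_mv = 5) {
  denom <- (v_hold_mv - junction_mv) - (e_rev_mv - junction_mv)
  if (abs(denom) < 1e-12) {
    stop("holding potential equals reversal potential: conductance undefined")
  }
  g <- i_pa / denom
  n_floored <- sum(g < 0)
  g[g < 0] <- 0
  list(g_ns = g, n_floored = n_floored)
}

#' Collapse per-direction excitatory conductances to a single untuned series
#'
#' Pointwise maximum across the recorded directions at each time point
#' (space-clamp errors reduce recorded excitatory currents, so the maximum
#' is the least-attenuated estimate).
#'
#' @param g_ex_dir matrix of excitatory conductances, nS (time in rows,
#'   directions in columns).
#' @return a single conductance series, nS.
#' @export
build_untuned_excitation <- function(g_ex_dir) {
  g_ex_dir <- as.matrix(g_ex_dir)
  if (ncol(g_ex_dir) != 8L) stop("expected 8 direction columns")
  do.call(pmax, as.data.frame(g_ex_dir))
}

#' Simulate the membrane response to one stimulus direction
#'
#' Forward-Euler integration of the parallel-conductance equation,
#' initialized at rest. `gain_ex` multiplies the excitatory conductance;
#' `gain_in` multiplies the inhibitory conductance of the simulated
#' direction (setting both to the same value emulates a contrast change).
#' An optional constant injected current `i_inj_pa` adds a conductance-free
#' depolarizing or hyperpolarizing term.
#'
#' @param set a [conductance_set()].
#' @param direction stimulus direction, degrees (one of `set$directions`).
#' @param gain_ex,gain_in non-negative gain factors.
#' @param mode `"spiking"` (threshold + 3 ms pause + reset to rest) or
#'   `"subthreshold"` (no spiking mechanism).
#' @param i_inj_pa constant injected current, pA (positive depolarizes).
#' @param dt integration step, seconds; defaults to the set's grid, and may
#'   be reduced (conductances are linearly interpolated onto the finer
#'   grid). Must divide the refractory period into an integer number of
#'   steps in spiking mode.
#' @return an object of class `membrane_trace`: `dt`, `time`, `vm` (mV),
#'   `spike_times` (s), `n_spikes`, `mode`.
#' @export
simulate_membrane <- function(set, direction, gain_ex = 1, gain_in = 1,
                              mode = c("spiking", "subthreshold"),
                              i_inj_pa = 0, dt = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "conductance_set"), gain_ex >= 0, gain_in >= 0)
  j <- match(direction, set$directions)
  if (is.na(j)) stop("`direction` is not one of the set's directions")
  if (is.null(dt)) dt <- set$dt
  if (dt <= 0) stop("`dt` must be positive")

  if (abs(dt - set$dt) < 1e-12) {
    gex <- gain_ex * set$g_ex
    gin <- gain_in * set$g_in[, j]
    time <- set$time
  } else {
    time <- seq(0, max(set$time), by = dt)
    gex <- gain_ex * stats::approx(set$time, set$g_ex, xout = time)$y
    gin <- gain_in * stats::approx(set$time, set$g_in[, j], xout = time)$y
  }
  n_refr <- 0L
  if (mode == "spiking") {
    steps <- set$t_refr_s / dt
    if (abs(steps - round(steps)) > 1e-9) {
      stop("`dt` must divide the refractory period into an integer number of steps")
    }
    n_refr <- as.integer(round(steps))
  }

  # dV = (dt/C) * (Gex*Eex + Gin*Ein + Grest*Erest + Iinj - V*(Gex+Gin+Grest))
  # units: nS * mV = pA; pA / pF * ms = mV
  dt_ms <- dt * 1000
  a <- dt_ms / set$C_pf *
    (gex * set$E_ex_mv + gin * set$E_in_mv +
       set$G_rest_ns * set$E_rest_mv + i_inj_pa)
  b <- dt_ms / set$C_pf * (gex + gin + set$G_rest_ns)

  n <- length(a)
  vm <- numeric(n)
  vm[1] <- set$E_rest_mv
  spikes <- numeric(0)
  i <- 1L
  if (mode == "subthreshold") {
    for (i in seq_len(n - 1L)) {
      vm[i + 1L] <- vm[i] + a[i] - b[i] * vm[i]
    }
  } else {
    while (i < n) {
      v_next <- vm[i] + a[i] - b[i] * vm[i]
      if (v_next > set$V_thresh_mv) {
        # spike onset at step i+1; pause for the refractory window, then
        # resume from rest
        vm[i + 1L] <- v_next
        spikes <- c(spikes, time[i + 1L])
        i_resume <- i + 1L + n_refr
        if (i_resume > n) {
          if (i + 2L <= n) vm[(i + 2L):n] <- set$E_rest_mv
          i <- n
          break
        }
        vm[(i + 2L):i_resume] <- set$E_rest_mv
        i <- i_resume
      } else {
        vm[i + 1L] <- v_next
        i <- i + 1L
      }
    }
  }
  structure(list(dt = dt, time = time, vm = vm, spike_times = spikes,
                 n_spikes = length(spikes), mode = mode),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace> %s mode, %d samples at %g ms, %d spikes\n",
              x$mode, length(x$vm), x$dt * 1000, x$n_spikes))
  invisible(x)
}

#' Time-above-threshold spike proxy
#'
#' Total duration a subthreshold-mode membrane trace spends above the spike
#' threshold. The spike count evoked by a stimulus is approximately linearly
#' proportional to this duration, so it serves as a reset-free alternative
#' to the explicit spiking mechanism.
#'
#' @param trace a `membrane_trace` (subthreshold mode).
#' @param v_thresh_mv threshold, mV.
#' @return time above threshold, seconds.
#' @export
proxy_spike_count <- function(trace, v_thresh_mv) {
  stopifnot(inherits(trace, "membrane_trace"))
  sum(trace$vm > v_thresh_mv) * trace$dt
}

#' Peak subthreshold depolarization for each direction
#'
#' Runs the model in subthreshold mode for all 8 directions and returns the
#' per-direction peak depolarization above rest (mV, floored at 0) as a
#' [directional_response()].
#'
#' @inheritParams simulate_membrane
#' @return a `directional_response` with unit `"mV"`.
#' @keywords internal
model_vm_curve <- function(set, gain_ex = 1, gain_in = 1, i_inj_pa = 0) {
  peaks <- vapply(set$directions, function(d) {
    tr <- simulate_membrane(set, d, gain_ex, gain_in, mode = "subthreshold",
                            i_inj_pa = i_inj_pa)
    max(0, max(tr$vm) - set$E_rest_mv)
  }, numeric(1))
  directional_response(peaks, directions = set$directions, unit = "mV")
}

#' Spike tuning curve of the model
#' @inheritParams simulate_membrane
#' @return a `directional_response` with unit `"spikes"`.
#' @keywords internal
model_spike_curve <- function(set, gain_ex = 1, gain_in = 1, i_inj_pa = 0,
                              v_thresh_mv = NULL) {
  if (!is.null(v_thresh_mv)) set$V_thresh_mv <- v_thresh_mv
  counts <- vapply(set$directions, function(d) {
    simulate_membrane(set, d, gain_ex, gain_in, mode = "spiking",
                      i_inj_pa = i_inj_pa)$n_spikes
  }, numeric(1))
  directional_response(counts, directions = set$directions, unit = "spikes")
}

#' Model preferred/null directions from the conductance structure
#' @keywords internal
model_pd_nd <- function(set) {
  pd <- set$directions[which.min(apply(set$g_in, 2, max))]
  c(pd = pd, nd = wrap360(pd + 180))
}

#' Gain sweep of the parallel-conductance model
#'
#' Simulates spike and peak-Vm tuning curves for all 8 directions at each
#' gain. In `"excitation-only"` mode the gain multiplies only the excitatory
#' conductance; in `"joint-EI"` mode it multiplies both the excitatory and
#' each inhibitory conductance (a contrast manipulation that preserves E/I).
#' Tuning metrics follow the zero-spike conventions (DSI 1, areas 0 when no
#' direction evokes a spike); Vm metrics are `NA` when the Vm curve is
#' identically zero.
#'
#' @param set a [conductance_set()].
#' @param gains non-negative gain values (non-empty).
#' @param mode `"excitation-only"` or `"joint-EI"`.
#' @return a data.frame with one row per gain: `gain`, `pd_spikes`,
#'   `nd_spikes`, `vm_peak_pd`, `vm_peak_nd` (mV above rest), `dsi_spk`,
#'   `dsi_vm`, `norm_area_spk`, `norm_area_vm`, `area_spk`, `area_vm`, and
#'   logical `threshold_regime` marking gains where a null-direction
#'   stimulus evokes zero spikes while the preferred direction evokes some.
#' @export
sweep_gain <- function(set, gains, mode = c("excitation-only", "joint-EI")) {
  mode <- match.arg(mode)
  if (length(gains) == 0) stop("`gains` must be non-empty")
  stopifnot(all(gains >= 0))
  ref <- model_pd_nd(set)
  j_pd <- match(ref[["pd"]], set$directions)
  j_nd <- match(ref[["nd"]], set$directions)

  rows <- lapply(gains, function(g) {
    ge <- g
    gi <- if (mode == "joint-EI") g else 1
    spk <- model_spike_curve(set, gain_ex = ge, gain_in = gi)
    vm <- model_vm_curve(set, gain_ex = ge, gain_in = gi)
    vm_zero <- all(vm$response == 0)
    data.frame(
      gain = g,
      pd_spikes = spk$response[j_pd], nd_spikes = spk$response[j_nd],
      vm_peak_pd = vm$response[j_pd], vm_peak_nd = vm$response[j_nd],
      dsi_spk = direction_selectivity_index(spk),
      dsi_vm = if (vm_zero) NA_real_ else direction_selectivity_index(vm),
      norm_area_spk = normalized_area(spk),
      norm_area_vm = if (vm_zero) NA_real_ else normalized_area(vm),
      area_spk = linear_tuning_area(spk),
      area_vm = linear_tuning_area(vm)
    )
  })
  out <- do.call(rbind, rows)
  out$threshold_regime <- out$nd_spikes == 0 & out$pd_spikes > 0
  attr(out, "pd_deg") <- ref[["pd"]]
  attr(out, "mode") <- mode
  out
}

#' Calibrate the spike threshold to target tuning metrics
#'
#' Searches for the threshold at which the model's spike tuning curve (at
#' the given excitatory gain) matches target values of the direction
#' selectivity index and normalized tuning-curve area, by minimizing the
#' equally weighted sum of squared errors of the two metrics over a
#' deterministic coarse-to-fine grid between rest and the peak
#' preferred-direction membrane potential.
#'
#' @param set a [conductance_set()].
#' @param target_dsi,target_norm_area target spike-tuning metrics.
#' @param gain_ex excitatory gain at which to calibrate (default 1).
#' @param step_mv resolution of the fine grid, mV (default 0.05).
#' @return list with `v_thresh_mv`, `objective`, `dsi`, `norm_area`, and
#'   logical `at_boundary` (`TRUE`, with a warning, when the optimum sits at
#'   an end of the search interval).
#' @export
calibrate_threshold <- function(set, target_dsi, target_norm_area,
                                gain_ex = 1, step_mv = 0.05) {
  vm_pd <- max(vapply(set$directions, function(d) {
    max(simulate_membrane(set, d, gain_ex, mode = "subthreshold")$vm)
  }, numeric(1)))
  lo <- set$E_rest_mv + 0.25
  hi <- vm_pd - 1e-6
  if (hi <= lo) stop("no supra-rest depolarization: nothing to calibrate")

  objective <- function(th) {
    spk <- model_spike_curve(set, gain_ex = gain_ex, v_thresh_mv = th)
    (direction_selectivity_index(spk) - target_dsi)^2 +
      (normalized_area(spk) - target_norm_area)^2
  }
  coarse <- seq(lo, hi, by = max(step_mv, (hi - lo) / 60))
  obj_c <- vapply(coarse, objective, numeric(1))
  th0 <- coarse[which.min(obj_c)]
  fine <- seq(max(lo, th0 - (coarse[2] - coarse[1])),
              min(hi, th0 + (coarse[2] - coarse[1])), by = step_mv)
  obj_f <- vapply(fine, objective, numeric(1))
  best <- which.min(obj_f)
  th <- fine[best]
  at_boundary <- th <= lo + step_mv || th >= hi - step_mv
  if (at_boundary) {
    warning("calibrated threshold lies at the boundary of the search interval")
  }
  spk <- model_spike_curve(set, gain_ex = gain_ex, v_thresh_mv = th)
  list(v_thresh_mv = th, objective = obj_f[best],
       dsi = direction_selectivity_index(spk),
       norm_area = normalized_area(spk), at_boundary = at_boundary)
}

#' Isolate spikes from a current-clamp voltage trace
#'
#' Locates action potentials from the first derivative of the voltage trace
#' (onset where dV/dt first exceeds `dvdt_thresh`), finds each spike's
#' offset as the first post-peak sample where the voltage falls back to the
#' onset level or the derivative turns non-negative after the
#' repolarization, enforces a minimum refractory period between onsets
#' (events closer than `min_refractory_s` merge into one), and linearly
#' interpolates the subthreshold voltage across each spike.
#'
#' @param vm voltage trace, mV, uniformly sampled.
#' @param dt sample interval, seconds.
#' @param min_refractory_s minimum separation between spike onsets.
#' @param dvdt_thresh onset threshold on dV/dt, mV/ms (default 10).
#' @param max_width_s upper bound on a single spike's onset-to-offset
#'   extent, seconds (default 5 ms), bounding the afterhyperpolarization
#'   bridge.
#' @return list with `spike_times` (onset times, s) and `vm_interp` (the
#'   trace with spikes bridged by linear interpolation).
#' @export
isolate_subthreshold <- function(vm, dt, min_refractory_s = 0.003,
                                 dvdt_thresh = 10, max_width_s = 0.005) {
  if (anyNA(vm)) stop("voltage trace contains NA")
  n <- length(vm)
  dvdt <- c(diff(vm) / (dt * 1000), 0) # mV/ms
  above <- dvdt > dvdt_thresh
  onsets <- which(above & !c(FALSE, above[-n]))
  if (length(onsets) == 0) {
    return(list(spike_times = numeric(0), vm_interp = vm))
  }
  # merge onsets within the refractory period
  keep <- c(TRUE, diff(onsets) * dt >= min_refractory_s)
  onsets <- onsets[keep]

  vm_out <- vm
  times <- numeric(0)
  last_off <- 0L
  for (on in onsets) {
    if (on <= last_off) next # swallowed by the previous spike's extent
    v_on <- vm[on]
    # find the spike peak, then the offset: the end of repolarization (the
    # local minimum where the derivative turns back up), extended through
    # any fast afterhyperpolarization recovery
    i <- on
    while (i < n && dvdt[i] > 0) i <- i + 1L # peak: derivative turns negative
    off <- i
    while (off < n && vm[off] > v_on && dvdt[off] < 0) off <- off + 1L
    # bridge any afterhyperpolarization: extend (bounded by max_width_s)
    # until the voltage recovers to the onset level
    max_off <- min(n, on + as.integer(round(max_width_s / dt)))
    while (off < max_off && vm[off] < v_on) off <- off + 1L
    if (off >= n) off <- n
    times <- c(times, (on - 1L) * dt)
    idx <- on:off
    vm_out[idx] <- vm[on] + (vm[off] - vm[on]) *
      (idx - on) / max(1L, off - on)
    last_off <- off
  }
  list(spike_times = times, vm_interp = vm_out)
}

#' Subthreshold-voltage tuning curve
#'
#' The maximum voltage deflection from baseline per direction, floored at 0
#' and averaged over repeats when several traces per direction are given.
#'
#' @param traces a list of 8 elements (one per direction, in the order of
#'   `directions`); each element is a numeric vm trace (mV) or a matrix of
#'   repeats (repeats in columns).
#' @param baseline_mv baseline potential, mV.
#' @param directions direction labels, degrees.
#' @return a `directional_response` with unit `"mV"`.
#' @export
vm_tuning_curve <- function(traces, baseline_mv,
                            directions = seq(0, 315, by = 45)) {
  if (length(traces) != 8L) stop("need one trace (or repeat matrix) per direction")
  peaks <- vapply(traces, function(tr) {
    m <- as.matrix(tr)
    mean(apply(m, 2, function(v) max(0, max(v) - baseline_mv)))
  }, numeric(1))
  directional_response(peaks, directions = directions, unit = "mV")
}
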