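# retinokr

Tools for linking the direction tuning of ON direction-selective retinal
ganglion cells (oDSGCs) to the vertical optokinetic reflex (OKR).

Vertical OKR in the mouse is asymmetric: superior-moving gratings evoke
stronger tracking (higher gain) than inferior-moving ones, and the asymmetry
shrinks at low contrast. The retinal substrate is a pair of cell types
projecting to the medial terminal nucleus — Superior and Inferior oDSGCs —
whose spike tuning curves differ in size and width. `retinokr` implements
the computational chain that connects these observations:

- **Direction-tuning statistics.** Preferred direction (vector sum of the
  eight-direction responses), direction selectivity index
  `DSI = |Σ mₖ e^{iθₖ}| / Σ mₖ`, linear and preferred-direction-normalized
  tuning-curve areas (circular trapezoid integral / 360°), width at 50 %
  response, Von Mises fits `a·e^{κ cos(x−μ)} / (2π I₀(κ))`, and the
  Superior/Inferior/excluded classification rule (DSI > 0.05, preferred
  direction > 30° from the temporal–nasal axis).
- **Parallel-conductance model.** A single-compartment membrane
  `C dV/dt = G_ex(E_ex−V) + G_in(E_in−V) + G_rest(E_rest−V)` driven by
  eight direction-specific inhibitory conductances and one untuned
  excitatory conductance, integrated by forward Euler at 1 ms with a spike
  threshold, 3 ms refractory pause, and reset to rest. Includes conductance
  extraction from clamp currents (Ohm's law with junction correction),
  excitatory and joint E+I gain sweeps, threshold calibration against
  target tuning metrics, a time-above-threshold spike proxy, spike
  isolation from current-clamp traces, and subthreshold-voltage tuning
  curves.
- **Eye kinematics.** Pupil-landmark to angular eye position
  (`θ = arcsin(Δy/R_p0)`, `ϕ = arcsin(Δx/√(R_p0²−Δy²))`), saccade (fast
  nystagmus) detection from velocity/acceleration thresholds, saccade
  removal by velocity substitution and reintegration, slow-phase OKR gain
  per half-oscillation (eye velocity / stimulus velocity), and
  fast/slow-nystagmus statistics with baseline-drift estimation.
- **Retina-to-behavior prediction.** Bootstrap deltas between Superior
  preferred-direction and Inferior null-direction response distributions
  (and vice versa) for the four drifting-bar conditions; instantaneous
  Superior−Inferior rate subtraction integrated to predicted eye position
  `p(t) = ∫(Sup − Inf) dt`; the four-parameter base-10 sigmoid nonlinearity
  `v(r) = v_min + (v_max−v_min)/(1+10^{(r₅₀−r)m})`; and the
  permutation-consistency analysis over scrambled condition assignments.
- **Retinal mosaics.** Hard-core mosaic simulation in a circular model
  retina (15 µm somata, noisy coverage-factor exclusion zones), Rodieck
  density recovery profiles with exact circular edge correction, retina
  center/radius estimation from perimeter-point triples, and normalized
  polar retinal coordinates.
- **Synthetic data.** Every module can be exercised without recorded data:
  generators for stimulus waveforms, oDSGC populations with the observed
  effect structure, conductance sets, oscillation-cycle firing rates, and
  eye traces with ground-truth saccades. All generators are pure functions
  of their parameters and a seed.

## Worked example

Sweep the excitatory gain of the packaged model cell and read off how the
spike threshold sculpts direction tuning:

```r
library(retinokr)
set <- make_conductance_set("Superior")
sw <- sweep_gain(set, c(0.6, 1.0, 1.4))
sw[, c("gain", "pd_spikes", "nd_spikes", "dsi_spk", "dsi_vm", "threshold_regime")]
#>   gain pd_spikes nd_spikes dsi_spk dsi_vm threshold_regime
#> 1  0.6         7         0   0.676 0.1429             TRUE
#> 2  1.0        50         0   0.269 0.1128             TRUE
#> 3  1.4        85        41   0.109 0.0971            FALSE
```

At gains 0.6 and 1.0 the null direction stays below threshold while the
preferred direction spikes increasingly — the nonlinear regime in which
spike tuning (DSI falling from 0.68 to 0.27) is far sharper than the nearly
gain-invariant membrane-potential tuning (DSI ≈ 0.11–0.14). Predict OKR
gain from a synthetic population with the observed effect structure:

```r
pop <- make_population(seed = 1)
pred <- predict_bar_conditions(response_distributions(pop),
                               n_boot = 10000, seed = 1)
pred$conditions
#>       condition  delta ci_lo  ci_hi
#> 1 superior_high 22.792 21.79 24.903
#> 2 inferior_high 11.859 10.87 12.958
#> 3  superior_low  2.038  1.84  2.559
#> 4  inferior_low  0.161  0.00  0.342
pred$orderings
#>   gain_decreases_with_contrast superior_exceeds_inferior_high
#>                           TRUE                           TRUE
#>          asymmetry_shrinks_low
#>                           TRUE
```

The deltas (median Superior preferred-direction minus Inferior
null-direction spike counts, in spikes) are relative gain predictions: gain
falls with contrast, superior stimuli beat inferior ones at high contrast,
and the asymmetry shrinks at low contrast.

## Layout

- `R/` — implementation (tuning, conductance model, eye kinematics,
  prediction, mosaics, synthetic data, table IO / pipeline runner)
- `tests/testthat/` — unit, property, and end-to-end suites with
  independent oracles
- `vignettes/retina-to-okr-methods.Rmd` — model assumptions, parameter
  choices, and numerical conventions
- `scripts/acceptance.R` — end-to-end reproduction script
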