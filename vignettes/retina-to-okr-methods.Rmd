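---
title: "From retinal direction tuning to optokinetic behavior: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From retinal direction tuning to optokinetic behavior: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinokr)
```

## The scientific problem

Vertical optokinetic reflex (OKR) behavior in the mouse — slow tracking eye
movements interleaved with resetting saccades — is driven by two retinal
cell types, Superior and Inferior ON direction-selective ganglion cells
(oDSGCs), which project to the medial terminal nucleus and prefer
dorsal-to-ventral and ventral-to-dorsal motion on the retina respectively.
The two channels are not mirror images: Superior oDSGCs spike more and have
broader tuning curves. `retinokr` implements the analysis chain that turns
this cellular asymmetry into quantitative behavioral predictions, together
with the biophysical model that explains where the asymmetry in spike
tuning comes from, and synthetic-data generators so that every stage can be
exercised and tested without recorded data.

## Direction-tuning statistics

A cell's `directional_response` holds its mean responses to eight motion
directions 45° apart. All metrics descend from two circular statistics:

- the **preferred direction** is the angle of the resultant
  $\sum_k m_k e^{i\theta_k}$ — not necessarily the single probed direction
  with the largest response;
- the **direction selectivity index** is the resultant length divided by
  the scalar sum, 0 for a flat curve and 1 for a one-direction cell.

Curve *areas* are circular integrals divided by 360°. We integrate with the
trapezoid rule including the wraparound segment from 315° back to
360° ≡ 0°; for equally spaced directions this equals the response mean, but
the explicit wraparound keeps the convention correct for interpolated
curves. A rectangle-rule alternative is exposed (`method = "rectangle"`)
because the two rules weight isolated peaks differently; for delta-like
curves on an even grid they coincide.

Normalization divides all eight responses by the response *at the preferred
direction*; when that direction falls between probed directions, the
preferred response is linearly interpolated between the two flanking
directions. A perfectly uniform curve has no unique preferred direction but
every direction carries the preferred response, so its normalized curve is
defined as all ones (and its normalized area exactly 1).

**Zero-spike conventions.** Cells that fire no spikes in any direction (as
happens at low contrast) take linear area 0, normalized area 0, and DSI 1.
These are the limits the metrics approach as the total spike count
approaches zero, and the thresholded conductance model reproduces them. The
conventions are for spike data only: an all-zero subthreshold-voltage curve
raises an error instead, since a flat membrane potential carries no such
limiting behavior.

**Von Mises fits** use the circular Gaussian
$a\,e^{\kappa\cos(x-\mu)}/(2\pi I_0(\kappa))$ with a free amplitude $a$,
because raw tuning curves are not normalized densities. The amplitude
enters linearly and is profiled out in closed form; $(\mu, \log\kappa)$ are
then optimized by Nelder–Mead from a fixed 8 × 3 grid of starts (the eight
probed directions; $\kappa_0 \in \{0.5, 2, 8\}$), which makes the fit
deterministic and robust to the multimodality of the residual surface.

**Classification.** A labeled cell is an oDSGC when its spike DSI exceeds
0.05 and its preferred direction lies more than 30° from the temporal–nasal
axis; it is Superior when the preferred direction has a ventral (retinal)
component, Inferior when dorsal. The retinal frame is configurable; the
default puts nasal at 0° and dorsal at 90°, and visual-space directions are
the 180° inversion of retinal ones (the lens inverts the image).

## The parallel-conductance model

A single-compartment membrane,

$$C\,\frac{dV}{dt} = G_{ex}(t)\,(E_{ex}-V) + G_{in}(t)\,(E_{in}-V) +
  G_{rest}\,(E_{rest}-V) + I_{inj},$$

is driven by one untuned excitatory conductance and eight per-direction
inhibitory conductances, integrated with forward Euler at a 1 ms step from
$V(0)=E_{rest}$. In spiking mode, when $V$ surpasses the threshold a spike
is counted, integration pauses for 3 ms (the spike plus refractory period),
and $V$ resumes from rest; this literal pause-and-reset is the model's
defining nonlinearity. Because resetting also changes synaptic driving
forces, a reset-free proxy is provided: the time the non-spiking trace
spends above threshold, to which spike counts are approximately
proportional.

Conductances derive from voltage-clamp currents by Ohm's law
$G = I/(V_{hold}-E_{rev})$; the 5 mV liquid-junction correction applies to
both potentials and cancels in the difference. Negative conductances
(clamp noise) are floored at zero and counted. The untuned excitatory
conductance is the pointwise maximum across the eight recorded directions
— space-clamp error attenuates recorded excitation, so the maximum is the
least-attenuated estimate.

Defaults for the packaged synthetic cell: $E_{rest} = -54$ mV (current
injections of about ±6 mV around this value bracket the physiological
range), $E_{ex} = 0$ mV, $E_{in} = -60$ mV (the excitation-isolation
holding potential), $C = 60$ pF, $G_{rest} = 6.67$ nS (150 MΩ input
resistance), spike threshold $-46.2$ mV, refractory 3 ms, step 1 ms.

**Gain sweeps.** `sweep_gain()` multiplies the excitatory conductance alone
(`excitation-only`) or excitation and all inhibitions together
(`joint-EI`, which preserves E/I and emulates a contrast change). The
*threshold regime* — gains at which the null direction evokes zero spikes
while the preferred direction spikes — is flagged per gain: inside it,
spike tuning sharpens dramatically while membrane-potential tuning barely
moves, the core thresholding phenomenon.

**Threshold calibration.** `calibrate_threshold()` finds the threshold at
which the model's spike DSI and normalized area match target values, by an
equally weighted squared-error objective over a deterministic
coarse-to-fine grid between rest and the peak preferred-direction
potential (0.05 mV resolution). Spike counts are integers, so the objective
is piecewise constant; a grid is the appropriate search and recovers known
thresholds to within its resolution.

**Spike isolation.** Action potentials in current-clamp traces are located
from the first voltage derivative (onset where $dV/dt$ first exceeds
10 mV/ms — configurable, as recording conditions vary), with the offset at
the end of repolarization extended through any fast afterhyperpolarization
until the voltage recovers to onset level, bounded by a 5 ms maximum spike
extent. Onsets closer than the minimum refractory period merge into one
event. The subthreshold voltage is bridged linearly across each spike; Vm
tuning curves then take the per-direction maximum deflection from baseline,
floored at zero and averaged over repeats.

## Eye kinematics

Angular eye position follows from the tracked pupil-to-eye-center
displacement and the pupil's radius of rotation $R_{p0}$:
$\theta = \arcsin(\Delta y / R_{p0})$ vertically and
$\phi = \arcsin\!\big(\Delta x / \sqrt{R_{p0}^2-\Delta y^2}\big)$
horizontally. $R_{p0}$ varies with pupil size; `fit_rp0()` fits the
standard linear calibration. Only $\theta$ feeds the downstream analyses.

Saccades are detected where eye speed exceeds 50°/s or acceleration
2000°/s², with runs closer than 50 ms merged; the thresholds are
conventions (the upstream tracking pipeline does not fix them) and are
configurable and recorded in pipeline output. Removal substitutes the
velocity immediately before each saccade onset across the saccade and
reintegrates from the original starting position, so slow-phase
displacement is preserved; an interval starting at the first sample has no
pre-onset velocity, uses zero, and is flagged.

Slow-phase gain is computed per half-oscillation stage (superior stage:
positive stimulus velocity) as the ratio of mean eye velocity to mean
stimulus velocity. A regression-through-origin estimator is available
behind a flag; on clean data the two agree, and the stage-mean form is the
default because it is robust to brief residual artifacts. Baseline drift is
the median desaccaded eye velocity during the static-grating flanks, and
drift subtraction is applied only to oscillating-grating epochs: the
estimate presumes a near-neutral mean eye position, which unidirectional
stimuli violate.

## Retina-to-behavior prediction

For drifting bars, the relative gain predicted for (say) high-contrast
superior motion is the bootstrap delta between Superior preferred-direction
and Inferior null-direction responses: both populations respond to that
stimulus in those directions. Each of 10,000 iterations resamples both
arrays with replacement and takes the difference of medians; the estimate
is the median of the delta distribution with a 95 % percentile interval.
Resampling is across cells (per-cell mean responses), the reading most
consistent with population-level inference; each cell contributes its own
preferred/null responses (computed from its high-contrast curve and read
off by circular interpolation), with a fixed-axis alternative provided.

Three qualitative orderings summarize the behavioral prediction: gain
decreases with contrast; superior exceeds inferior at high contrast; and
the superior−inferior gap shrinks at low contrast.
`permutation_consistency()` asks how specific these orderings are to the
true assignment of cellular responses: each of the four behavioral
conditions is independently assigned one of four delta sources (which cell
type is the minuend × which contrast), a $4^4 = 256$ assignment space, and
assignments satisfying all orderings are counted. The enumeration is one
plausible reading of "scrambling assignments" and is configurable through
the predicate; the exact count of consistent permutations depends on the
population realization and should be read as a small fraction, not a fixed
integer.

For oscillating gratings, the median Superior and Inferior population
rates on a 5 ms grid are subtracted point by point; the difference is a
linear prediction of eye velocity, and its cumulative trapezoidal integral
(starting at 0°) predicts eye position. Velocity units are arbitrary
(spikes/s differences); only orderings and the fitted nonlinearity map to
°/s. That nonlinearity is the base-10 sigmoid
$v(r) = v_{min} + (v_{max}-v_{min}) / (1 + 10^{(r_{50}-r)\,m})$ — written
with the division, the only reading under which $v_{min}$ and $v_{max}$
are asymptotes and $r_{50}$ the inflection, matching the parameters'
stated meanings. Fitting profiles $v_{min}, v_{max}$ (linear given
$r_{50}, m$) over a fixed start grid ($r_{50}$ at the data quartiles,
$m \in \{0.01, 0.05, 0.2\}$), polishes all four parameters with BFGS, and
canonicalizes to $m > 0$ using the parameterization's swap symmetry. For
the four bar conditions an origin point (0, 0) is appended
(`add_origin = TRUE`). Identifiability caveat: when the sigmoid is shallow
relative to the sampled range, $r_{50}$ is weakly constrained and noisy
fits scatter widely; the parameter-recovery tests therefore use a sigmoid
whose transition lies well inside the sampled range.

## Retinal mosaics

`generate_mosaics()` places somata sequentially by rejection sampling in a
circular model retina (default radius 2000 µm, matching a whole-mount; 669
cells, the typical labeled count), under two constraints: a hard monolayer
core (center spacing at least twice the 15 µm soma radius) for *all*
pairs, and a noisy exclusion zone for *same-mosaic* pairs set by the
mosaic's coverage factor. The exclusion radius is the mean
nearest-neighbor distance of a random field at the mosaic's density,
$0.5/\sqrt{\lambda}$, jittered per candidate (Gaussian, SD 15 µm, floored
at the hard core). This choice keeps the packing fraction of exclusion
discs at $\pi/16 \approx 0.20$ at any density — safely below the ~0.55
jamming limit of sequential placement. The regular-lattice spacing
$\sqrt{2/(\sqrt3\,\lambda)}$, an alternative exclusion scale, implies a
packing fraction near 0.9 at these densities and cannot be realized by
rejection sampling, which is why the random-field spacing is used.
Placement order is randomized across mosaics; the retry budget is 10,000
per cell, and exhaustion is an error reporting the achieved count, never a
silent shortfall.

Density recovery profiles count, for every cell, neighbors in concentric
annuli (default 10 µm bins, resolving the 30 µm hard core) and divide by
the annulus areas summed over reference cells. Near the retina edge
annuli extend beyond the field; the default clips each annulus to the
retina disc with exact circle-intersection geometry, keeping the estimator
unbiased at the boundary (`edge_correction = "none"` reproduces the
uncorrected estimator for interior-dominated fields). The discriminating
signature: one mosaic empties its exclusion ring (30–60 µm) while unions
of independent mosaics progressively fill it.

The retina frame for cross-retina comparison comes from eight perimeter
points: the center is the componentwise median of all point-triple
circumcenters and the radius the median circumradius, with near-collinear
triples skipped; positions are then expressed in normalized polar
coordinates (radius fraction, angle from the dorsal axis).

## The synthetic-data generators

The generators emulate the *structure* of the recorded data — effect
directions and orders of magnitude — not its full biological variability.

- **Stimuli.** Oscillating epochs are 20 s static, 120 s of
  $A\sin(2\pi t/T)$ position (defaults $A = 20°$, $T = 15$ s: exactly
  eight cycles), 20 s static; unidirectional epochs 20/60/20 s at 10°/s.
  Velocity is stored as the exact forward difference of position so that
  integration round-trips bit-exactly.
- **Populations.** Each cell's drive is a Von Mises profile scaled by a
  lognormal cell gain; the mean spike response subtracts a fixed
  rectification offset and floors at zero, so reducing contrast both
  shrinks and sharpens curves — the same thresholding motif the
  conductance model makes explicit, and the reason the zero-spike
  conventions arise naturally at low contrast. Defaults: 116 Superior and
  170 Inferior cells; Superior drive 30 versus Inferior 18 spikes with
  widths $\kappa$ 1.8 versus 3.2 (Superior larger and broader); contrast
  factors 1 and 0.2; Poisson trial noise (counts are non-negative
  integers), with a negative-binomial option since trial-to-trial
  dispersion of oDSGC responses is not characterized.
- **Conductance sets.** Inhibition rises earlier and decays faster than
  excitation (onset 0.4 versus 0.5 s; time constants 0.05/0.35 versus
  0.15/0.5 s): it overlaps the rising phase of excitation but not its
  peak, so peak-Vm tuning is weakly gain-dependent while spike output,
  integrating the whole suprathreshold epoch, remains strongly tuned —
  the regime in which the thresholding results are cleanest. Peak
  inhibition 8 nS with inverted-Von-Mises direction weighting (sharper in
  Superior, $\kappa$ 3 versus 2); peak excitation 2.0 nS (Superior) versus
  1.4 nS (Inferior), weakly weighted ($\kappa = 0.2$) before the pointwise
  maximum collapses it to a single untuned trace.
- **Rates and eye traces.** Population rates are half-wave-rectified
  copies of the stimulus velocity (Superior gain 20 Hz, Inferior 12 Hz at
  peak speed) plus optional Gaussian noise; eye traces integrate
  gain × stimulus velocity plus drift and white velocity noise, with
  resetting saccades at Poisson times and ground-truth interval labels.

What the generators do *not* emulate: receptive-field spatial structure,
response latency differences between cell types, adaptation across
repeats, correlated trial noise, torsional eye movements, or blink/groom
artifacts in eye traces. Tests passing on synthetic data therefore
validate the *algorithms* (estimators recover known ground truth;
invariants hold), not the biological effect sizes.

## Problem sizes and determinism

Test and reproduction runs use desk-scale sizes chosen to exercise every
code path: populations at the full 286-cell scale; 10,000 bootstrap
iterations for the headline predictions and 400–2,000 for auxiliary
checks; 160 s eye traces at 200 Hz; 4 s conductance traces at 1 kHz;
mosaics at the full 669-cell scale. Every stochastic function takes a
seed, and child seeds derive from the run seed by a fixed counter scheme
(`derive_seed()`), so identical configurations are bit-identical — a
property the pipeline runner asserts by checksum.

## Known limitations

- The membrane model is single-compartment: no dendritic spikes, kinetic
  receptor models, or space-clamp correction; these are known
  contributors to oDSGC tuning that the model deliberately omits.
- The refractory handling holds the membrane at rest for the full pause;
  the time-above-threshold proxy exists precisely because reset semantics
  perturb driving forces.
- The prediction chain is algorithmic, not mechanistic: it stops at the
  retina's output and does not model downstream oculomotor dynamics.
- Saccade-detection thresholds and the permutation-space enumeration are
  conventions; both are configurable, and conclusions should be checked
  for robustness to them.
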