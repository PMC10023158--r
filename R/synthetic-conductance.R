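#' Synthetic conductance set for the parallel-conductance model
#'
#' Builds the per-direction inhibitory and single untuned excitatory
#' conductance waveforms of a model oDSGC responding to a drifting bar, with
#' the structure of the recorded inputs: inhibition is strongly direction
#' tuned (minimal in the preferred direction, maximal in the null
#' direction), excitation is at most weakly tuned, and Superior cells
#' receive larger excitation than Inferior cells at similar inhibition.
#'
#' Each channel's temporal waveform is an alpha-like difference of
#' exponentials `exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise)`
#' normalized to unit peak. Inhibition rises earlier and faster than
#' excitation (as expected for the feedforward inhibition evoked by an
#' approaching bar), so it overlaps the rising phase of the excitatory
#' response but has largely decayed by its peak: the peak membrane
#' depolarization is then only weakly direction dependent while spike
#' output — which integrates the whole suprathreshold epoch — remains
#' strongly tuned. Per-direction inhibitory peak amplitudes follow an
#' inverted Von Mises weighting `exp(kappa_in (cos(theta - null) - 1))`;
#' excitation is generated per direction with a weak Von Mises weighting
#' (`kappa_ex`) and collapsed to a single untuned series by the pointwise
#' maximum across directions ([build_untuned_excitation()]).
#'
#' Membrane constants default to physiological values for mouse
#' MTN-projecting ganglion cells: rest -54 mV, excitatory reversal 0 mV,
#' inhibitory reversal -60 mV, capacitance 60 pF, leak 6.67 nS (150 Mohm
#' input resistance), spike threshold -46.2 mV, refractory period 3 ms,
#' integration step 1 ms.
#'
#' @param cell_type `"Superior"` or `"Inferior"`; selects the excitatory
#'   gain (2.0 vs 1.4 nS) and inhibitory tuning width (3.0 vs 2.0;
#'   Superior inhibition is more sharply tuned) defaults.
#' @param g_ex_peak_ns peak excitatory conductance, nS; default per type.
#' @param g_in_peak_ns peak (null-direction) inhibitory conductance, nS.
#' @param kappa_in Von Mises width of the inhibitory direction weighting;
#'   default per type.
#' @param kappa_ex width of the weak excitatory direction weighting.
#' @param pref_dir_deg preferred direction, degrees (minimum inhibition).
#' @param tau_rise_ex_s,tau_decay_ex_s,onset_ex_s excitatory kernel rise /
#'   decay time constants and onset, seconds.
#' @param tau_rise_in_s,tau_decay_in_s,onset_in_s inhibitory kernel
#'   parameters, seconds (earlier and faster than excitation by default).
#' @param duration_s trace duration, seconds.
#' @param amp_noise_cv per-direction multiplicative amplitude jitter
#'   (lognormal CV; 0 disables noise).
#' @param dt integration grid, seconds (default 0.001).
#' @param E_ex_mv,E_in_mv,E_rest_mv reversal and rest potentials, mV.
#' @param C_pf capacitance, pF.
#' @param G_rest_ns leak conductance, nS.
#' @param V_thresh_mv spike threshold, mV.
#' @param t_refr_s refractory period, seconds.
#' @param seed integer seed for the amplitude jitter.
#' @return an object of class `conductance_set`; see [conductance_set()].
#' @examples
#' set <- make_conductance_set("Superior")
#' sweep_gain(set, c(0.5, 1))
#' @export
make_conductance_set <- function(cell_type = c("Superior", "Inferior"),
                                 g_ex_peak_ns = NULL,
                                 g_in_peak_ns = 8,
                                 kappa_in = NULL,
                                 kappa_ex = 0.2,
                                 pref_dir_deg = 270,
                                 tau_rise_ex_s = 0.15, tau_decay_ex_s = 0.5,
                                 onset_ex_s = 0.5,
                                 tau_rise_in_s = 0.05, tau_decay_in_s = 0.35,
                                 onset_in_s = 0.4,
                                 duration_s = 4,
                                 amp_noise_cv = 0,
                                 dt = 0.001,
                                 E_ex_mv = 0, E_in_mv = -60, E_rest_mv = -54,
                                 C_pf = 60, G_rest_ns = 6.67,
                                 V_thresh_mv = -46.2, t_refr_s = 0.003,
                                 seed = 1) {
  cell_type <- match.arg(cell_type)
  if (is.null(g_ex_peak_ns)) {
    g_ex_peak_ns <- if (cell_type == "Superior") 2.0 else 1.4
  }
  if (is.null(kappa_in)) {
    kappa_in <- if (cell_type == "Superior") 3.0 else 2.0
  }
  stopifnot(g_ex_peak_ns >= 0, g_in_peak_ns >= 0, kappa_in >= 0,
            kappa_ex >= 0, amp_noise_cv >= 0)
  directions <- seq(0, 315, by = 45)
  time <- seq(0, duration_s, by = dt)
  kernel <- function(onset, tau_r, tau_d) {
    k <- exp(-pmax(time - onset, 0) / tau_d) - exp(-pmax(time - onset, 0) / tau_r)
    k[time < onset] <- 0
    k / max(k)
  }
  kern_in <- kernel(onset_in_s, tau_rise_in_s, tau_decay_in_s)
  kern_ex <- kernel(onset_ex_s, tau_rise_ex_s, tau_decay_ex_s)

  set.seed(derive_seed(seed, 1L))
  jit <- function(n) {
    if (amp_noise_cv == 0) rep(1, n) else
      stats::rlnorm(n, -0.5 * log(1 + amp_noise_cv^2),
                    sqrt(log(1 + amp_noise_cv^2)))
  }
  null_dir <- wrap360(pref_dir_deg + 180)
  w_in <- exp(kappa_in * (cos(deg2rad(directions - null_dir)) - 1)) * jit(8)
  g_in <- outer(kern_in, g_in_peak_ns * w_in)
  w_ex <- exp(kappa_ex * (cos(deg2rad(directions - pref_dir_deg)) - 1)) * jit(8)
  g_ex_dir <- outer(kern_ex, g_ex_peak_ns * w_ex)
  g_ex <- build_untuned_excitation(g_ex_dir)

  conductance_set(dt = dt, g_in = g_in, g_ex = g_ex, directions = directions,
                  E_ex_mv = E_ex_mv, E_in_mv = E_in_mv, E_rest_mv = E_rest_mv,
                  C_pf = C_pf, G_rest_ns = G_rest_ns,
                  V_thresh_mv = V_thresh_mv, t_refr_s = t_refr_s,
                  meta = list(cell_type = cell_type, seed = seed,
                              pref_dir_deg = pref_dir_deg))
}
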