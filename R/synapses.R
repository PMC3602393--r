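# Kinetic synapse primitives (closed-form surface).
#
# The network integrator evolves the same dual-exponential kinetics
# event-by-event through a pair of exponential state variables; these
# functions are the analytic reference for single synapses and are used by
# the analysis layer and the test-suite.

#' Describe a single synapse
#'
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA_A"`.
#' @param g_max_nS peak conductance (the dual exponential is
#'   peak-normalised, so `g_max` is attained exactly at the peak for a unit
#'   weight).
#' @param weight dimensionless multiplier (>= 0).
#' @param tau1,tau2 rise and decay time constants, ms; `tau2 > tau1 > 0`.
#' @param e_rev reversal potential, mV.
#' @param delay_ms axonal + synaptic delay, ms.
#' @param subtype_tag `"alpha2_initial_segment"` only for GABA_A synapses on
#'   the pyramidal initial segment; `"other"` otherwise.
#' @param params parameter list supplying per-kind defaults.
#' @return object of class `hg_synapse_spec`.
#' @export
synapse_spec <- function(kind = c("AMPA", "NMDA", "GABA_A"),
                         g_max_nS = NULL, weight = 1, tau1 = NULL,
                         tau2 = NULL, e_rev = NULL, delay_ms = NULL,
                         subtype_tag = "other",
                         params = default_params()) {
  kind <- match.arg(kind)
  d <- params$synapses[[kind]]
  g_max_nS <- g_max_nS %||% d$g_max_nS
  tau1 <- tau1 %||% d$tau1_ms
  tau2 <- tau2 %||% d$tau2_ms
  e_rev <- e_rev %||% d$e_rev_mV
  delay_ms <- delay_ms %||% d$delay_ms
  abort_if(tau1 <= 0 || tau2 <= tau1,
           "synapse time constants must satisfy tau2 > tau1 > 0")
  abort_if(g_max_nS < 0 || weight < 0,
           "g_max and weight must be nonnegative")
  abort_if(subtype_tag == "alpha2_initial_segment" && kind != "GABA_A",
           "alpha2_initial_segment tag is only valid on GABA_A synapses")
  structure(list(kind = kind, g_max_nS = g_max_nS, weight = weight,
                 tau1 = tau1, tau2 = tau2, e_rev = e_rev,
                 delay_ms = delay_ms, subtype_tag = subtype_tag),
            class = "hg_synapse_spec")
}

#' Dual-exponential conductance after a single event
#'
#' `g(t) = weight * g_max * N * (exp(-t / tau2) - exp(-t / tau1))`, with `N`
#' normalising the peak to 1 so `g_max` is the literal peak conductance.
#' Events superpose linearly.
#'
#' @param t_since_event time since the event arrived, ms (vectorised).
#' @param spec an [synapse_spec()].
#' @return conductance in nS.
#' @export
dual_exp_conductance <- function(t_since_event, spec) {
  abort_if(any(t_since_event < 0), "t_since_event must be >= 0")
  N <- dual_exp_norm(spec$tau1, spec$tau2)
  spec$weight * spec$g_max_nS * N *
    (exp(-t_since_event / spec$tau2) - exp(-t_since_event / spec$tau1))
}

#' Voltage-dependent NMDA magnesium block (Jahr-Stevens)
#'
#' `1 / (1 + [Mg] / 3.57 * exp(-0.062 V))`; monotonically increasing in V,
#' identically 1 without magnesium.
#'
#' @param v membrane potential, mV (vectorised).
#' @param mg_conc extracellular magnesium, mM.
#' @return unblocked fraction in (0, 1].
#' @export
nmda_gate <- function(v, mg_conc = 1) {
  abort_if(mg_conc < 0, "mg_conc must be >= 0")
  1 / (1 + (mg_conc / 3.57) * exp(-0.062 * v))
}

#' Synaptic current from an event history
#'
#' `I = g(t) * (V_post - E_rev)`, with the NMDA kind additionally
#' multiplied by [nmda_gate()]. Linear in the synapse weight and additive
#' over events.
#'
#' @param spec an [synapse_spec()].
#' @param events event arrival times, ms (sorted).
#' @param t evaluation time, ms.
#' @param v_post postsynaptic potential, mV.
#' @param mg_conc magnesium, mM (NMDA only).
#' @return current in nA (positive outward).
#' @export
synaptic_current <- function(spec, events, t, v_post, mg_conc = 1) {
  abort_if(is.unsorted(events), "events must be sorted by time")
  past <- events[events <= t]
  g <- if (length(past)) sum(dual_exp_conductance(t - past, spec)) else 0
  if (spec$kind == "NMDA") g <- g * nmda_gate(v_post, mg_conc)
  g * (v_post - spec$e_rev) * 1e-3  # nS * mV = pA; report nA
}
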