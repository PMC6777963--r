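#' Neuron model parameters
#'
#' Parameters of the current-based leaky integrate-and-fire neuron. The
#' membrane potential decays toward its resting value `v_0` (shifted by any
#' imposed polarization) with time constant `tau_m`, jumps by the synaptic
#' amplitude on each arriving spike, and on reaching `v_th` emits a spike,
#' resets to `v_reset` and stays clamped for the refractory period `t_ref`.
#'
#' @param tau_m Membrane time constant, ms.
#' @param t_ref Absolute refractory period, ms.
#' @param v_0 Resting potential, mV.
#' @param v_reset Post-spike reset potential, mV.
#' @param v_th Firing threshold, mV.
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(tau_m = 10, t_ref = 2, v_0 = 0, v_reset = 10,
                          v_th = 20) {
  stopifnot(tau_m > 0, t_ref >= 0)
  if (!(v_0 <= v_reset && v_reset < v_th)) {
    stop("neuron parameters must satisfy v_0 <= v_reset < v_th", call. = FALSE)
  }
  structure(list(tau_m = tau_m, t_ref = t_ref, v_0 = v_0,
                 v_reset = v_reset, v_th = v_th),
            class = "neuron_params")
}

#' Network model parameters
#'
#' Sizes, static wiring rule, synaptic amplitudes and external drive of the
#' recurrent network. All connections involving inhibitory neurons are
#' static; excitatory-to-excitatory connections start empty and are grown by
#' the structural-plasticity rule.
#'
#' Two static wiring rules are supported. `"bernoulli"` draws every ordered
#' pair independently with the block's connection probability (the rule used
#' at full scale, 10% probability). `"fixed_indegree"` draws, for every
#' target neuron, a fixed number of source neurons with replacement
#' (multapses allowed). Down-scaled networks use fixed in-degrees equal to
#' the full-scale expectation so that the mean and variance of the recurrent
#' input per neuron — and with them the homeostatic operating point — are
#' preserved when only the neuron count shrinks; see the package vignette.
#'
#' @param n_e,n_i Number of excitatory / inhibitory neurons.
#' @param gamma_ei,gamma_ie,gamma_ii Static connection probabilities
#'   (E to I, I to E, I to I) used by the `"bernoulli"` rule.
#' @param k_ei,k_ie,k_ii Static in-degrees per target neuron used by the
#'   `"fixed_indegree"` rule (number of E inputs per I neuron, I inputs per
#'   E neuron, I inputs per I neuron).
#' @param j_e Excitatory postsynaptic potential amplitude, mV (> 0).
#' @param j_i Inhibitory postsynaptic potential amplitude, mV (< 0).
#' @param j_ext Amplitude of external-drive synapses, mV; defaults to `j_e`.
#' @param r_ext External Poisson rate per neuron, spikes/s.
#' @param d Synaptic transmission delay, ms; must be a positive multiple of
#'   `dt`.
#' @param dt Integration step, ms.
#' @param wiring Static wiring rule, `"bernoulli"` or `"fixed_indegree"`.
#' @return An object of class `network_config`.
#' @seealso [network_preset()] for the catalogued full-scale and desk-scale
#'   configurations.
#' @examples
#' network_config(n_e = 100, n_i = 25)
#' @export
network_config <- function(n_e, n_i,
                           gamma_ei = 0.1, gamma_ie = 0.1, gamma_ii = 0.1,
                           k_ei = NULL, k_ie = NULL, k_ii = NULL,
                           j_e = 0.1, j_i = -0.8, j_ext = j_e,
                           r_ext = 30000, d = 1, dt = 0.1,
                           wiring = c("bernoulli", "fixed_indegree")) {
  wiring <- match.arg(wiring)
  stopifnot(n_e >= 1, n_i >= 0, dt > 0, r_ext >= 0)
  if (!(j_e > 0)) stop("j_e must be positive", call. = FALSE)
  if (!(j_i < 0)) stop("j_i must be negative", call. = FALSE)
  for (g in c(gamma_ei, gamma_ie, gamma_ii)) {
    if (g < 0 || g > 1) stop("connection probabilities must lie in [0, 1]",
                             call. = FALSE)
  }
  d_steps <- d / dt
  if (d <= 0 || abs(d_steps - round(d_steps)) > 1e-9) {
    stop("delay d must be a positive integer multiple of dt", call. = FALSE)
  }
  if (wiring == "fixed_indegree" &&
      (is.null(k_ei) || is.null(k_ie) || is.null(k_ii))) {
    stop("fixed_indegree wiring requires k_ei, k_ie and k_ii", call. = FALSE)
  }
  structure(list(n_e = as.integer(n_e), n_i = as.integer(n_i),
                 gamma_ei = gamma_ei, gamma_ie = gamma_ie, gamma_ii = gamma_ii,
                 k_ei = k_ei, k_ie = k_ie, k_ii = k_ii,
                 j_e = j_e, j_i = j_i, j_ext = j_ext, r_ext = r_ext,
                 d = d, dt = dt, wiring = wiring),
            class = "network_config")
}

#' Structural plasticity parameters
#'
#' The homeostat tracks each excitatory neuron's firing rate through an
#' intracellular calcium trace `C` that jumps by `beta_ca` per spike and
#' decays exponentially with time constant `tau_ca`. Presynaptic and
#' postsynaptic synaptic elements grow at rate `nu * (1 - C / eps)`:
#' below the calcium set point `eps` new elements are produced, above it
#' elements are removed and the synapses they were bound in are broken.
#' At the set point the target firing rate is `eps / (beta_ca * tau_ca)`
#' (8 Hz with the defaults).
#'
#' @param eps Calcium set point (dimensionless trace units).
#' @param nu Element growth rate, elements per second.
#' @param tau_ca Calcium decay time constant, s.
#' @param beta_ca Calcium increment per spike.
#' @param dt_struct Structural update cadence, s. Synapse creation and
#'   deletion are resolved at this cadence; with `tau_ca` three orders of
#'   magnitude larger, the discretization error is negligible.
#' @return An object of class `plasticity_params`.
#' @examples
#' p <- plasticity_params()
#' target_rate(p) # 8 Hz
#' @export
plasticity_params <- function(eps = 0.008, nu = 4, tau_ca = 10,
                              beta_ca = 1e-4, dt_struct = 0.1) {
  stopifnot(eps > 0, tau_ca > 0, beta_ca > 0, dt_struct > 0, nu >= 0)
  structure(list(eps = eps, nu = nu, tau_ca = tau_ca, beta_ca = beta_ca,
                 dt_struct = dt_struct),
            class = "plasticity_params")
}

#' Homeostatic target firing rate
#'
#' The firing rate at which the calcium trace equilibrates at its set point:
#' `eps / (beta_ca * tau_ca)`.
#'
#' @param plasticity A [plasticity_params()] object.
#' @return Target rate in spikes/s.
#' @export
target_rate <- function(plasticity = plasticity_params()) {
  plasticity$eps / (plasticity$beta_ca * plasticity$tau_ca)
}

#' Catalogued network configurations
#'
#' `scale = 1` reproduces the full-size network (10,000 excitatory and 2,500
#' inhibitory neurons, 10% random static wiring). Smaller scales shrink the
#' neuron counts proportionally but keep every per-neuron quantity — synaptic
#' amplitudes, external rate, and the static in-degrees (1,000 E inputs per I
#' neuron, 250 I inputs per neuron) — so the mean-field operating point of
#' the full network is preserved and the homeostatic set point remains
#' reachable. Static multapses make the fixed in-degrees realizable at any
#' scale.
#'
#' @param scale Linear down-scaling factor for the neuron counts, in (0, 1].
#' @param ... Overrides passed on to [network_config()].
#' @return A [network_config()] object.
#' @examples
#' network_preset(scale = 0.1) # the desk-scale default: 1,000 E + 250 I
#' @export
network_preset <- function(scale = 0.1, ...) {
  stopifnot(scale > 0, scale <= 1)
  n_e <- as.integer(round(10000 * scale))
  n_i <- as.integer(round(2500 * scale))
  if (scale == 1) {
    network_config(n_e = n_e, n_i = n_i, wiring = "bernoulli", ...)
  } else {
    network_config(n_e = n_e, n_i = n_i, wiring = "fixed_indegree",
                   k_ei = 1000L, k_ie = 250L, k_ii = 250L, ...)
  }
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("LIF network: %d excitatory + %d inhibitory neurons\n",
              x$n_e, x$n_i))
  if (x$wiring == "bernoulli") {
    cat(sprintf("  static wiring: Bernoulli, Gamma(E-I, I-E, I-I) = (%g, %g, %g)\n",
                x$gamma_ei, x$gamma_ie, x$gamma_ii))
  } else {
    cat(sprintf("  static wiring: fixed in-degree, K(E->I, I->E, I->I) = (%d, %d, %d)\n",
                x$k_ei, x$k_ie, x$k_ii))
  }
  cat(sprintf("  J_E = %g mV, J_I = %g mV, r_ext = %g Hz, d = %g ms, dt = %g ms\n",
              x$j_e, x$j_i, x$r_ext, x$d, x$dt))
  invisible(x)
}
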