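#' Fresh network state
#'
#' Membrane potentials start at the resting value, the spike buffer is empty,
#' calcium traces and element counters are zero, and the plastic E-to-E
#' matrix has no synapses (networks are grown from scratch).
#'
#' @param config A [network_config()].
#' @param neuron A [neuron_params()].
#' @return A list holding the full mutable state of a simulation: membrane
#'   potentials `v`, refractory clocks `refr`, the delayed-spike ring buffer,
#'   the E-to-E synapse-count matrix `a`, calcium traces and element pools.
#' @keywords internal
new_network_state <- function(config, neuron = neuron_params()) {
  n <- config$n_e + config$n_i
  d_steps <- as.integer(round(config$d / config$dt))
  list(
    v = rep(neuron$v_0, n),
    refr = integer(n),
    buffer = matrix(0, nrow = n, ncol = d_steps),
    slot = 0L,
    a = matrix(0L, nrow = config$n_e, ncol = config$n_e),
    calcium = numeric(config$n_e),
    z_pre = numeric(config$n_e),
    z_post = numeric(config$n_e),
    free_pre = integer(config$n_e),
    free_post = integer(config$n_e),
    steps_mod_struct = 0L
  )
}

# Assemble the flat config list consumed by the C++ engine.
engine_cfg <- function(config, neuron, plasticity, wiring, duration_s,
                       plastic = TRUE, threshold_on = TRUE,
                       rate_ceiling = 0, ceiling_sustain = 5L) {
  list(
    n_e = config$n_e, n_i = config$n_i,
    dt_ms = config$dt, tau_m = neuron$tau_m,
    t_ref_steps = as.integer(round(neuron$t_ref / config$dt)),
    v_th = neuron$v_th, v_reset = neuron$v_reset,
    j_e = config$j_e, j_i = config$j_i, j_ext = config$j_ext,
    r_ext = config$r_ext,
    delay_steps = as.integer(round(config$d / config$dt)),
    threshold_on = threshold_on,
    plastic = plastic,
    nu = plasticity$nu, eps = plasticity$eps,
    tau_ca = plasticity$tau_ca, beta_ca = plasticity$beta_ca,
    struct_steps = as.integer(round(plasticity$dt_struct * 1000 / config$dt)),
    rate_ceiling = rate_ceiling, ceiling_sustain = as.integer(ceiling_sustain),
    static_ptr = wiring$src_ptr, static_tgt = wiring$tgt,
    duration_s = duration_s
  )
}

# Membership vector for the engine: 0-based group per neuron, -1 for
# inhibitory neurons (insensitive to polarization, not part of any group).
engine_membership <- function(config, assignment) {
  c(as.integer(assignment$membership) - 1L, rep(-1L, config$n_i))
}

# Run one simulation phase. `segments` is a data.frame with columns
# t_start (s, ascending, first row 0) and one column per group (mV).
run_phase <- function(state, config, neuron, plasticity, wiring, assignment,
                      duration_s, segments = NULL, plastic = TRUE,
                      threshold_on = TRUE, window_s = 5, trace_every_s = 1,
                      record_spikes = FALSE, record_v = FALSE,
                      rate_ceiling = 0, ceiling_sustain = 5L) {
  g <- assignment$n_groups
  if (is.null(segments)) {
    times <- 0
    values <- matrix(0, nrow = 1, ncol = g)
  } else {
    times <- segments$t_start
    values <- as.matrix(segments[, -1, drop = FALSE])
    stopifnot(ncol(values) == g, times[1] == 0, !is.unsorted(times))
  }
  cfg <- engine_cfg(config, neuron, plasticity, wiring, duration_s,
                    plastic = plastic, threshold_on = threshold_on,
                    rate_ceiling = rate_ceiling,
                    ceiling_sustain = ceiling_sustain)
  sched <- list(times = times, values = values,
                membership = engine_membership(config, assignment))
  rec <- list(window_s = window_s, trace_every_s = trace_every_s,
              record_spikes = record_spikes, record_v = record_v)
  out <- cpp_run_phase(state, cfg, sched, rec)
  out$window_s <- window_s
  out
}

#' Per-neuron Poisson input counts for one integration step
#'
#' The external drive is delivered as independent Poisson event counts per
#' neuron and step; each event adds `j_ext` to the membrane potential.
#'
#' @param rate External rate, spikes/s (per neuron).
#' @param dt Step width, ms.
#' @param n_neurons Number of neurons.
#' @return Integer vector of event counts.
#' @examples
#' set.seed(1)
#' mean(poisson_drive(18100, 0.1, 1e4)) # about 1.81
#' @export
poisson_drive <- function(rate, dt, n_neurons) {
  if (rate < 0) stop("external rate must be non-negative", call. = FALSE)
  stopifnot(dt > 0, n_neurons >= 1)
  rpois(n_neurons, rate * dt / 1000)
}

#' Simulate one background-driven neuron under membrane polarization
#'
#' A single LIF neuron receives Poisson background input (18.1 kHz through
#' 0.1 mV synapses by default, giving a fluctuating subthreshold free
#' membrane potential with mean `rate * tau_m * j_ext` = 18.1 mV) while its
#' membrane is polarized by `delta_v * cos(theta)`, where `theta` is the
#' angle between the electric field and the somato-dendritic axis. This is
#' the single-neuron dose-response experiment underlying the network
#' stimulation protocols.
#'
#' @param delta_v Membrane polarization magnitude, mV.
#' @param theta Field angle, radians; the effective bias is
#'   `delta_v * cos(theta)`.
#' @param duration Simulated time, s.
#' @param rate Background Poisson rate, spikes/s.
#' @param j_ext Background synapse amplitude, mV.
#' @param neuron A [neuron_params()].
#' @param dt Integration step, ms.
#' @param seed Optional seed.
#' @param threshold If `FALSE` the spike mechanism is disabled and the free
#'   membrane potential is tracked instead (useful to verify the analytic
#'   mean).
#' @param record_spikes Keep individual spike times.
#' @return A list with the firing `rate` (spikes/s), `n_spikes`, the
#'   time-averaged membrane potential `mean_v` (mV), and optionally
#'   `spike_t_ms`.
#' @examples
#' simulate_single_neuron(0, duration = 5, seed = 1)$rate
#' @export
simulate_single_neuron <- function(delta_v = 0, theta = 0, duration = 100,
                                   rate = 18100, j_ext = 0.1,
                                   neuron = neuron_params(), dt = 0.1,
                                   seed = NULL, threshold = TRUE,
                                   record_spikes = FALSE) {
  stopifnot(duration > 0, rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  bias <- delta_v * cos(theta)
  out <- cpp_single_neuron(duration, rate, j_ext, bias,
                           neuron$tau_m, neuron$t_ref, neuron$v_th,
                           neuron$v_reset, dt, threshold, record_spikes)
  out$bias <- bias
  out
}
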