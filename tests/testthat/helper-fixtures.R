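# Shared fixtures. Network property tests run on a down-scaled preset (the
# homeostatic set point is size-intensive; see the methods vignette); growing
# a network is the expensive step, so grown checkpoints are cached per
# (fractions, seed) and reused across stimulation arms within the suite.

.grown_cache <- new.env(parent = emptyenv())

# scale used by the network property tests
prop_scale <- 0.04

grown_fixture <- function(fractions, seed, scale = prop_scale, t_grow = 750) {
  key <- paste0("s", scale, "_f", paste(fractions, collapse = "_"), "_", seed)
  if (is.null(.grown_cache[[key]])) {
    .grown_cache[[key]] <- grow_network(network_preset(scale),
                                        fractions = fractions,
                                        t_grow = t_grow, seed = seed)
  }
  .grown_cache[[key]]
}

# a tiny configuration for fast mechanical tests (not a dynamical fixture)
tiny_network <- function(n_e = 10, n_i = 3, r_ext = 30000, ...) {
  network_config(n_e = n_e, n_i = n_i, wiring = "bernoulli", ...)
}

# run the engine directly on a prepared state (unit-level access)
run_engine <- function(state, config, duration_s, plastic = TRUE,
                       neuron = neuron_params(),
                       plasticity = plasticity_params(), wiring = NULL,
                       assignment = NULL, ...) {
  if (is.null(wiring)) wiring <- build_static_wiring(config, seed = 1)
  if (is.null(assignment)) assignment <- assign_groups(config$n_e, 1)
  tdcsnet:::run_phase(state, config, neuron, plasticity, wiring, assignment,
                      duration_s = duration_s, plastic = plastic, ...)
}
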