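#' Read a run configuration file
#'
#' A run is fully described by one YAML or JSON document with blocks
#' `network`, `neuron`, `plasticity`, `protocol`, and optional scalars
#' `seed` and `n_trials`. Field names mirror the constructor arguments
#' ([network_config()], [neuron_params()], [plasticity_params()],
#' [protocol_schedule()]); omitted fields take the model defaults. A
#' `network` block may instead give `scale` to use [network_preset()].
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file.
#' @return A list with elements `network`, `neuron`, `plasticity`,
#'   `schedule`, `seed`, `n_trials`, ready for [run_experiment()].
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' writeLines('{
#'   "network": {"scale": 0.02},
#'   "protocol": {"mode": "uni", "fractions": [0.1, 0.9],
#'                "delta_v": [0.1, 0], "t_grow": 20,
#'                "t_stim": 5, "t_relax": 5},
#'   "seed": 1
#' }', cfg)
#' read_run_config(cfg)$schedule
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(block, fn) {
    if (is.null(block)) return(fn())
    do.call(fn, block)
  }
  network <- if (!is.null(raw$network$scale)) {
    args <- raw$network
    scale <- args$scale
    args$scale <- NULL
    do.call(network_preset, c(list(scale = scale), args))
  } else {
    build(raw$network, network_config)
  }
  schedule <- if (is.null(raw$protocol)) NULL else {
    do.call(protocol_schedule, raw$protocol)
  }
  list(network = network,
       neuron = build(raw$neuron, neuron_params),
       plasticity = build(raw$plasticity, plasticity_params),
       schedule = schedule,
       seed = raw$seed,
       n_trials = if (is.null(raw$n_trials)) 1L else as.integer(raw$n_trials))
}
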