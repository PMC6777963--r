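# Orchestration of the growth -> stimulation -> relaxation lifecycle.

window_rate_df <- function(win_counts, window_s, n_e, membership) {
  n <- nrow(win_counts)
  w <- ncol(win_counts)
  groups <- c(membership, rep.int(0L, n - n_e))  # 0 = inhibitory pool
  labels <- sort(unique(groups))
  out <- NULL
  for (g in labels) {
    sel <- groups == g
    rate <- colSums(win_counts[sel, , drop = FALSE]) / sum(sel) / window_s
    out <- rbind(out, data.frame(
      window = seq_len(w), t_mid = (seq_len(w) - 0.5) * window_s,
      group = if (g == 0) "inh" else paste0("g", g), rate = rate))
  }
  rownames(out) <- NULL
  out
}

trace_df <- function(res, g, t_offset = 0) {
  out <- data.frame(time = res$trace_time + t_offset)
  for (tgt in seq_len(g)) {
    for (src in seq_len(g)) {
      out[[paste0("conn_g", src, "_g", tgt)]] <-
        res$trace_blocks[, (tgt - 1) * g + src]
    }
  }
  out$conn_total <- res$trace_total
  out$calcium <- res$trace_calcium
  out$z <- res$trace_z
  out
}

#' Grow a network to its homeostatic equilibrium
#'
#' Starting from an empty E-to-E matrix, the structural-plasticity rule grows
#' synapses until the excitatory population reaches the calcium set point
#' (8 Hz with default parameters). The returned object is a checkpoint:
#' stimulation experiments continue from it via [stimulate_network()], so a
#' single grown network can serve several protocols.
#'
#' @param network A [network_config()]; defaults to the desk-scale preset.
#' @param neuron A [neuron_params()].
#' @param plasticity A [plasticity_params()].
#' @param fractions Group fractions for the later stimulation (groups are
#'   fixed before growth so connectivity blocks can be traced throughout).
#' @param t_grow Growth period, s.
#' @param seed Optional seed for wiring, assignment and simulation.
#' @param window_s Firing-rate window, s.
#' @param trace_every_s Connectivity sampling cadence, s.
#' @return An object of class `grown_network` holding the configuration, the
#'   full simulator state, and growth-phase rate and connectivity records.
#' @examples
#' \donttest{
#' net <- grow_network(network_preset(0.02), t_grow = 20, seed = 1)
#' }
#' @export
grow_network <- function(network = network_preset(), neuron = neuron_params(),
                         plasticity = plasticity_params(), fractions = 1,
                         t_grow = 750, seed = NULL, window_s = 5,
                         trace_every_s = 1) {
  if (!is.null(seed)) set.seed(seed)
  wiring <- build_static_wiring(network)
  assignment <- assign_groups(network$n_e, fractions)
  state <- new_network_state(network, neuron)
  res <- run_phase(state, network, neuron, plasticity, wiring, assignment,
                   duration_s = t_grow, plastic = TRUE, window_s = window_s,
                   trace_every_s = trace_every_s)
  structure(list(network = network, neuron = neuron, plasticity = plasticity,
                 wiring = wiring, assignment = assignment, state = res$state,
                 t_grow = t_grow, seed = seed,
                 rates = window_rate_df(res$window_counts, window_s,
                                        network$n_e, assignment$membership),
                 trace = trace_df(res, assignment$n_groups),
                 clamped = res$clamped),
            class = "grown_network")
}

#' Apply a stimulation protocol to a grown network
#'
#' Continues the simulation from a [grow_network()] checkpoint through the
#' stimulation and relaxation phases of `schedule` (the checkpoint itself is
#' not modified). Times in the returned records are absolute (growth period
#' included). If the population rate stays above `rate_ceiling` for
#' `ceiling_sustain` consecutive seconds the run aborts with an error of
#' class `tdcsnet_runaway` — the signature of a pathological, runaway
#' parameterization.
#'
#' @param grown A `grown_network`.
#' @param schedule A [protocol_schedule()]; its fractions must match the
#'   grown network's group assignment.
#' @param seed Optional seed for the stimulation-phase randomness.
#' @param window_s,trace_every_s Recording cadences, s.
#' @param record_spikes Keep the full spike record (memory-heavy; intended
#'   for small runs).
#' @param keep_state Keep the end-of-run simulator state in the result.
#' @param rate_ceiling Abort threshold for the excitatory population rate,
#'   spikes/s; 0 disables the guard.
#' @param ceiling_sustain Seconds the ceiling must be exceeded before
#'   aborting.
#' @return An object of class `tdcs_experiment` with windowed `rates`, the
#'   connectivity `trace`, the pre-stimulation `baseline` block connectivity,
#'   the final block connectivity, and timing metadata (`t_grow`, `t_off`:
#'   end of the last stimulation phase, absolute seconds).
#' @export
stimulate_network <- function(grown, schedule, seed = NULL, window_s = 5,
                              trace_every_s = 1, record_spikes = FALSE,
                              keep_state = FALSE, rate_ceiling = 0,
                              ceiling_sustain = 5) {
  stopifnot(inherits(grown, "grown_network"),
            inherits(schedule, "protocol_schedule"))
  if (length(schedule$fractions) != grown$assignment$n_groups ||
      any(abs(schedule$fractions - grown$assignment$fractions) > 1e-9)) {
    stop("schedule fractions do not match the grown network's groups",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  seg <- schedule_segments(schedule)
  duration <- attr(seg, "duration")
  res <- run_phase(grown$state, grown$network, grown$neuron, grown$plasticity,
                   grown$wiring, grown$assignment, duration_s = duration,
                   segments = seg, plastic = TRUE, window_s = window_s,
                   trace_every_s = trace_every_s,
                   record_spikes = record_spikes,
                   rate_ceiling = rate_ceiling,
                   ceiling_sustain = ceiling_sustain)
  if (isTRUE(res$aborted)) {
    stop(errorCondition(
      paste("population rate exceeded the ceiling for a sustained period;",
            "the network entered a runaway (pathological) state"),
      class = c("tdcsnet_runaway", "error", "condition")))
  }
  g <- grown$assignment$n_groups
  baseline <- matrix(as.numeric(tail(grown$trace, 1)[
    paste0("conn_g", rep(seq_len(g), g), "_g", rep(seq_len(g), each = g))]),
    g, g, dimnames = list(target = seq_len(g), source = seq_len(g)))
  final <- group_connectivity(res$state$a, grown$assignment)
  out <- list(schedule = schedule, assignment = grown$assignment,
              t_grow = grown$t_grow,
              t_off = grown$t_grow + attr(seg, "t_off"),
              duration = duration,
              rates = window_rate_df(res$window_counts, window_s,
                                     grown$network$n_e,
                                     grown$assignment$membership),
              trace = trace_df(res, g, t_offset = grown$t_grow),
              baseline = baseline, final = final,
              clamped = res$clamped)
  if (record_spikes) {
    out$spikes <- data.frame(id = res$spike_id,
                             t_ms = res$spike_t_ms + grown$t_grow * 1000)
  }
  if (keep_state) out$state <- res$state
  structure(out, class = "tdcs_experiment")
}

#' Run one complete stimulation experiment
#'
#' Convenience wrapper: grow a fresh network, then apply the schedule.
#' Identical configuration and seed give a bit-identical result bundle.
#'
#' @inheritParams grow_network
#' @inheritParams stimulate_network
#' @param seed Master seed for the whole run.
#' @return A `tdcs_experiment`; see [stimulate_network()].
#' @export
run_experiment <- function(schedule, network = network_preset(),
                           neuron = neuron_params(),
                           plasticity = plasticity_params(), seed = NULL,
                           window_s = 5, trace_every_s = 1,
                           record_spikes = FALSE, keep_state = FALSE,
                           rate_ceiling = 0, ceiling_sustain = 5) {
  grown <- grow_network(network, neuron, plasticity,
                        fractions = schedule$fractions,
                        t_grow = schedule$t_grow, seed = seed,
                        window_s = window_s, trace_every_s = trace_every_s)
  stimulate_network(grown, schedule, window_s = window_s,
                    trace_every_s = trace_every_s,
                    record_spikes = record_spikes, keep_state = keep_state,
                    rate_ceiling = rate_ceiling,
                    ceiling_sustain = ceiling_sustain)
}

#' Fit the relaxation-phase connectivity change of an experiment
#'
#' Extracts one connectivity block (within-group by default), subtracts the
#' pre-stimulation baseline, and fits the triple-exponential decay from the
#' end of the last stimulation phase. The fit's `i_g` is the connectivity
#' time integral used to compare protocols.
#'
#' @param experiment A `tdcs_experiment`.
#' @param source,target Group indices of the block (defaults: within group 1,
#'   the stimulated assembly).
#' @param ... Passed to [fit_triple_exponential()].
#' @return An `exp_fit`; see [fit_triple_exponential()].
#' @export
relaxation_fit <- function(experiment, source = 1, target = source, ...) {
  stopifnot(inherits(experiment, "tdcs_experiment"))
  col <- paste0("conn_g", source, "_g", target)
  y <- experiment$trace[[col]] - experiment$baseline[target, source]
  fit_triple_exponential(experiment$trace$time, y, t0 = experiment$t_off, ...)
}

#' Repeat an experiment over independent trials
#'
#' Runs `n_trials` independent grow-stimulate experiments with per-trial
#' seeds derived deterministically from the master seed, and summarizes the
#' within-group-1 connectivity (relative to each trial's own baseline) and,
#' optionally, the connectivity integral.
#'
#' @inheritParams run_experiment
#' @param n_trials Number of independent simulations.
#' @param fit Also compute the relaxation-phase `i_g` per trial.
#' @param grown Optional pre-grown network reused across trials (the trials
#'   then differ only in stimulation-phase randomness; the default regrows
#'   per trial).
#' @return A list with `trials` (one row per trial: final and baseline
#'   within-G1 connectivity, their difference, and `i_g` if requested) and
#'   `summary` (mean and sd per column).
#' @export
run_trials <- function(schedule, n_trials = 5, network = network_preset(),
                       neuron = neuron_params(),
                       plasticity = plasticity_params(), seed = 1,
                       fit = FALSE, grown = NULL, ...) {
  seeds <- seed + seq_len(n_trials) - 1L
  rows <- NULL
  for (k in seq_len(n_trials)) {
    exp_k <- if (is.null(grown)) {
      run_experiment(schedule, network, neuron, plasticity, seed = seeds[k],
                     ...)
    } else {
      stimulate_network(grown, schedule, seed = seeds[k], ...)
    }
    row <- data.frame(trial = k, seed = seeds[k],
                      baseline = exp_k$baseline[1, 1],
                      final = exp_k$final[1, 1],
                      change = exp_k$final[1, 1] - exp_k$baseline[1, 1])
    if (fit) row$i_g <- relaxation_fit(exp_k)$i_g
    rows <- rbind(rows, row)
  }
  num <- rows[, setdiff(names(rows), c("trial", "seed")), drop = FALSE]
  list(trials = rows,
       summary = data.frame(stat = c("mean", "sd"),
                            rbind(colMeans(num), apply(num, 2, sd))))
}

#' Sweep stimulation protocols over a grid
#'
#' Applies each schedule in `schedules` to the same grown network (fresh
#' stimulation-phase randomness per point) and tabulates the within-G1
#' connectivity outcome and its time integral. Failures at individual grid
#' points (runaway dynamics, failed fits) are recorded and the sweep
#' continues. With a single schedule the result row matches
#' [stimulate_network()] on the same grown network.
#'
#' @param grown A `grown_network` (see [grow_network()]); all schedules must
#'   use its group fractions.
#' @param schedules Named list of [protocol_schedule()] objects.
#' @param seed Base seed; point `k` uses `seed + k - 1`.
#' @param fit Compute `i_g` via [relaxation_fit()].
#' @param ... Passed to [stimulate_network()].
#' @return A data.frame with one row per grid point: `name`, `delta_v1`,
#'   `fraction1`, `final`, `baseline`, `change`, `i_g`, `error`.
#' @export
sweep_experiment <- function(grown, schedules, seed = 1, fit = TRUE, ...) {
  stopifnot(length(schedules) >= 1)
  if (is.null(names(schedules))) {
    names(schedules) <- paste0("run", seq_along(schedules))
  }
  rows <- NULL
  for (k in seq_along(schedules)) {
    sch <- schedules[[k]]
    row <- data.frame(name = names(schedules)[k], delta_v1 = sch$delta_v[1],
                      fraction1 = sch$fractions[1], final = NA_real_,
                      baseline = NA_real_, change = NA_real_, i_g = NA_real_,
                      error = NA_character_)
    res <- tryCatch(stimulate_network(grown, sch, seed = seed + k - 1, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$final <- res$final[1, 1]
      row$baseline <- res$baseline[1, 1]
      row$change <- row$final - row$baseline
      if (fit) {
        f <- tryCatch(relaxation_fit(res), error = function(e) NULL,
                      warning = function(w) NULL)
        if (!is.null(f) && !f$degenerate) row$i_g <- f$i_g
      }
    }
    rows <- rbind(rows, row)
  }
  rownames(rows) <- NULL
  rows
}

#' @export
print.grown_network <- function(x, ...) {
  last <- tail(x$rates[x$rates$group != "inh", ], x$assignment$n_groups)
  cat(sprintf("grown network (%d E + %d I), %g s growth\n",
              x$network$n_e, x$network$n_i, x$t_grow))
  cat(sprintf("  final E rate %.2f Hz, mean E-E connectivity %.4g\n",
              mean(last$rate), tail(x$trace$conn_total, 1)))
  invisible(x)
}

#' @export
print.tdcs_experiment <- function(x, ...) {
  cat(sprintf("tDCS experiment: %s protocol, %d cycle(s)\n",
              x$schedule$mode, x$schedule$n_cycles))
  cat(sprintf("  within-G1 connectivity: baseline %.4g -> final %.4g\n",
              x$baseline[1, 1], x$final[1, 1]))
  invisible(x)
}
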