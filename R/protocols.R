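#' Assign excitatory neurons to stimulation groups
#'
#' Partitions the excitatory population into disjoint groups covering all
#' neurons, uniformly at random. Group sizes are fixed deterministically by
#' largest-remainder rounding of the requested fractions, so e.g. fractions
#' (0.3, 0.3, 0.4) of 1,000 neurons give sizes (300, 300, 400) exactly.
#' Inhibitory neurons are never assigned: only excitatory neurons are taken
#' to be sensitive to the stimulation.
#'
#' @param n_e Number of excitatory neurons.
#' @param fractions Numeric vector of group fractions, summing to 1.
#' @param seed Optional seed; the assignment is reproducible from it.
#' @return An object of class `group_assignment` with `membership` (integer
#'   group label, 1-based, per excitatory neuron), `sizes` and `fractions`.
#' @examples
#' a <- assign_groups(1000, c(0.3, 0.3, 0.4), seed = 1)
#' a$sizes
#' @export
assign_groups <- function(n_e, fractions = 1, seed = NULL) {
  stopifnot(n_e >= 1, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("group fractions must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- length(fractions)
  quota <- n_e * fractions
  sizes <- floor(quota)
  rem <- n_e - sum(sizes)
  if (rem > 0) {
    top <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1
  }
  membership <- rep.int(seq_len(g), sizes)[sample.int(n_e)]
  structure(list(membership = as.integer(membership),
                 sizes = as.integer(sizes), fractions = fractions,
                 n_groups = g),
            class = "group_assignment")
}

#' Stimulation protocol schedule
#'
#' Describes one polarization protocol: which per-group membrane bias is
#' applied when. Stimulation always starts after the growth period; in
#' repetitive mode each cycle is `t_stim` seconds of stimulation followed by
#' `t_relax` seconds of pause (`"repetitive_on_off"`) or of opposite-polarity
#' stimulation of the same magnitude (`"repetitive_alternating"`). The
#' single-cycle modes `"uni"`, `"bi"` and `"tri"` differ only in how many
#' groups carry a nonzero bias. After the last cycle the network relaxes for
#' `t_post` seconds without stimulation.
#'
#' @param mode One of `"uni"`, `"bi"`, `"tri"`, `"repetitive_on_off"`,
#'   `"repetitive_alternating"`.
#' @param fractions Group fractions of the excitatory population (sum 1).
#' @param delta_v Per-group polarization, mV; same length as `fractions`.
#' @param t_grow Growth period, s.
#' @param t_stim Stimulation-on duration per cycle (t1), s.
#' @param t_relax Pause / opposite-phase duration per cycle (t2), s. For the
#'   single-cycle modes this is the relaxation period after stimulation.
#' @param n_cycles Number of stimulation cycles.
#' @param t_post Additional unstimulated relaxation after the last cycle, s.
#' @return An object of class `protocol_schedule`.
#' @examples
#' protocol_schedule("uni", fractions = c(0.1, 0.9), delta_v = c(0.1, 0),
#'                   t_stim = 150, t_relax = 300)
#' @export
protocol_schedule <- function(mode = c("uni", "bi", "tri",
                                       "repetitive_on_off",
                                       "repetitive_alternating"),
                              fractions, delta_v, t_grow = 750,
                              t_stim = 150, t_relax = 300, n_cycles = 1,
                              t_post = 0) {
  mode <- match.arg(mode)
  stopifnot(length(delta_v) == length(fractions),
            t_grow >= 0, t_stim >= 0, t_relax >= 0, n_cycles >= 1)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("group fractions must sum to 1", call. = FALSE)
  }
  n_groups_expected <- c(uni = NA, bi = 2, tri = 3)[mode]
  if (!is.na(n_groups_expected) && length(fractions) != n_groups_expected) {
    stop(sprintf("mode '%s' expects %d groups", mode, n_groups_expected),
         call. = FALSE)
  }
  if (mode %in% c("uni", "bi", "tri") && n_cycles != 1) {
    stop("single-cycle modes use n_cycles = 1", call. = FALSE)
  }
  structure(list(mode = mode, fractions = fractions, delta_v = delta_v,
                 t_grow = t_grow, t_stim = t_stim, t_relax = t_relax,
                 n_cycles = n_cycles, t_post = t_post),
            class = "protocol_schedule")
}

#' Piecewise-constant segments of a schedule
#'
#' Expands a [protocol_schedule()] into its breakpoints, in seconds since the
#' end of the growth period. Each row holds the per-group bias that applies
#' from `t_start` until the next breakpoint.
#'
#' @param schedule A [protocol_schedule()].
#' @return A data.frame with column `t_start` followed by one bias column per
#'   group, plus attributes `duration` (total seconds after growth) and
#'   `t_off` (time at which the last stimulation phase ends).
#' @export
schedule_segments <- function(schedule) {
  s <- schedule
  g <- length(s$fractions)
  zero <- rep(0, g)
  on <- s$delta_v
  off <- switch(s$mode, repetitive_alternating = -s$delta_v, zero)
  rows_t <- numeric(0)
  rows_v <- NULL
  t <- 0
  for (k in seq_len(s$n_cycles)) {
    rows_t <- c(rows_t, t, t + s$t_stim)
    rows_v <- rbind(rows_v, on, off)
    t <- t + s$t_stim + s$t_relax
  }
  t_off <- if (s$mode == "repetitive_alternating") t else t - s$t_relax
  rows_t <- c(rows_t, t)
  rows_v <- rbind(rows_v, zero)
  duration <- t + s$t_post
  out <- data.frame(t_start = rows_t)
  vals <- as.data.frame(rows_v)
  names(vals) <- paste0("g", seq_len(g))
  out <- cbind(out, vals)
  rownames(out) <- NULL
  # drop zero-length segments (e.g. t_relax = 0) and repeated breakpoints
  keep <- !duplicated(out$t_start, fromLast = TRUE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "duration") <- duration
  attr(out, "t_off") <- t_off
  out
}

#' Per-neuron polarization at a given time
#'
#' Evaluates the schedule at absolute simulation time `t` (seconds since the
#' start of the growth period): all zeros before `t_grow` and after the last
#' cycle, the group bias during on-phases, zero (on-off) or the opposite
#' polarity (alternating) in between.
#'
#' @param t Time, s, from the start of the simulation.
#' @param schedule A [protocol_schedule()].
#' @param assignment A [assign_groups()] result.
#' @return Numeric vector of biases (mV), one per excitatory neuron.
#' @export
delta_v_at <- function(t, schedule, assignment) {
  stopifnot(t >= 0, length(schedule$fractions) == assignment$n_groups)
  seg <- schedule_segments(schedule)
  tt <- t - schedule$t_grow
  g <- assignment$n_groups
  if (tt < 0 || tt >= attr(seg, "duration")) {
    per_group <- rep(0, g)
  } else {
    row <- findInterval(tt, seg$t_start)
    per_group <- as.numeric(seg[row, -1])
  }
  per_group[assignment$membership]
}

# --- catalogued protocol presets ------------------------------------------

preset_catalogue <- function() {
  list(
    fig2_depol = list(
      about = "uni-group, 10% depolarized by +0.1 mV, 150 s on, 300 s relax",
      schedule = protocol_schedule("uni", c(0.1, 0.9), c(0.1, 0),
                                   t_stim = 150, t_relax = 300)),
    fig2_hyper = list(
      about = "uni-group, 10% hyperpolarized by -0.1 mV, 150 s on, 300 s relax",
      schedule = protocol_schedule("uni", c(0.1, 0.9), c(-0.1, 0),
                                   t_stim = 150, t_relax = 300)),
    fig3_tri = list(
      about = "tri-group, 30% at +0.1 mV, 30% at -0.1 mV, 40% unstimulated",
      schedule = protocol_schedule("tri", c(0.3, 0.3, 0.4), c(0.1, -0.1, 0),
                                   t_stim = 150, t_relax = 300)),
    fig3_bi = list(
      about = "bi-group, 30% at +0.1 mV, 70% at -0.1 mV",
      schedule = protocol_schedule("bi", c(0.3, 0.7), c(0.1, -0.1),
                                   t_stim = 150, t_relax = 300)),
    fig4_intensity_grid = list(
      about = "focality x intensity sweeps, 150 s on, 5,850 s relax",
      intensities = c(-1.2, -0.8, -0.4, 0.4, 0.8, 1.2),
      focality = list(uni = c(0.1, 0.3, 0.5, 0.7),
                      bi = c(0.1, 0.3, 0.5, 0.7),
                      tri = c(0.1, 0.2, 0.3, 0.4)),
      t_stim = 150, t_relax = 5850),
    fig5_duty_grid = list(
      about = "repetitive on-off, total on-time 6,000 s split over cycles",
      t1_t2 = cbind(t1 = c(75, 75, 150, 150, 150, 300),
                    t2 = c(75, 150, 75, 150, 300, 150)),
      n_cycles = 6000 / c(75, 75, 150, 150, 150, 300),
      delta_v = 0.1),
    fig5_asymmetric = list(
      about = "repetitive on-off, 80 cycles of 75 s on / 150 s off",
      schedule = protocol_schedule("repetitive_on_off", c(0.1, 0.9),
                                   c(0.1, 0), t_stim = 75, t_relax = 150,
                                   n_cycles = 80),
      intensities = c(0.02, 0.04, 0.06, 0.08, 0.1, 0.2, 0.3, 0.4, 0.5)),
    fig6_on_off = list(
      about = "3 cycles on-off, 150 s / 150 s, +0.1 mV",
      schedule = protocol_schedule("repetitive_on_off", c(0.1, 0.9),
                                   c(0.1, 0), t_stim = 150, t_relax = 150,
                                   n_cycles = 3)),
    fig6_alternating1 = list(
      about = "3 cycles alternating +/-0.05 mV, 150 s / 150 s",
      schedule = protocol_schedule("repetitive_alternating", c(0.1, 0.9),
                                   c(0.05, 0), t_stim = 150, t_relax = 150,
                                   n_cycles = 3)),
    fig6_alternating2 = list(
      about = "3 cycles alternating +/-0.1 mV, 150 s / 150 s",
      schedule = protocol_schedule("repetitive_alternating", c(0.1, 0.9),
                                   c(0.1, 0), t_stim = 150, t_relax = 150,
                                   n_cycles = 3))
  )
}

#' Catalogued stimulation protocols
#'
#' Returns the preset matching one of the catalogued montage/protocol
#' configurations (uni-, bi- and tri-group scenarios, focality-intensity
#' sweeps, repetitive on-off and alternating-polarity cycles). Grid presets
#' (`fig4_intensity_grid`, `fig5_duty_grid`, `fig5_asymmetric`) return the
#' expanded parameter lists alongside any template schedule.
#'
#' @param name Preset name; see [list_presets()].
#' @return A list with at least an `about` string and, for single-protocol
#'   presets, a `schedule` ([protocol_schedule()]).
#' @examples
#' table4_preset("fig6_on_off")$schedule$n_cycles
#' @export
table4_preset <- function(name) {
  cat <- preset_catalogue()
  if (!name %in% names(cat)) {
    stop(sprintf("unknown preset '%s'; see list_presets()", name),
         call. = FALSE)
  }
  cat[[name]]
}

#' List the catalogued stimulation presets
#'
#' @return A data.frame with preset names and descriptions.
#' @export
list_presets <- function() {
  cat <- preset_catalogue()
  data.frame(preset = names(cat),
             description = vapply(cat, function(x) x$about, character(1)),
             row.names = NULL)
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("protocol '%s': fractions (%s), delta_v (%s) mV\n", x$mode,
              paste(x$fractions, collapse = ", "),
              paste(x$delta_v, collapse = ", ")))
  cat(sprintf("  growth %g s, %d cycle(s) of %g s on / %g s %s, then %g s free\n",
              x$t_grow, x$n_cycles, x$t_stim, x$t_relax,
              if (x$mode == "repetitive_alternating") "reversed" else "off",
              x$t_post))
  invisible(x)
}
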