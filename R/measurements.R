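#' Group firing rates from a spike record
#'
#' Rates are computed per neuron as spike count divided by the window length
#' over disjoint windows (5 s by default), then averaged arithmetically over
#' the members of each group.
#'
#' @param spikes A data.frame with columns `id` (neuron, 1-based) and `t_ms`
#'   (spike time, ms), e.g. as returned in experiment results.
#' @param membership Integer group label per neuron (1-based); neurons are
#'   `seq_along(membership)`.
#' @param window Window length, s.
#' @param t_end End of the recording, s; defaults to the last full window.
#' @return A data.frame with columns `window` (index), `t_mid` (s), `group`
#'   and `rate` (spikes/s).
#' @examples
#' sp <- data.frame(id = rep(1L, 40), t_ms = seq(100, 4900, length.out = 40))
#' firing_rate(sp, membership = c(1L, 1L), window = 5) # 40/5/2 neurons = 4 Hz
#' @export
firing_rate <- function(spikes, membership, window = 5, t_end = NULL) {
  stopifnot(window > 0, length(membership) >= 1)
  groups <- sort(unique(membership))
  counts_by_group <- table(factor(membership, levels = groups))
  if (any(counts_by_group == 0)) {
    stop("firing rate of an empty group is undefined", call. = FALSE)
  }
  if (is.null(t_end)) {
    t_end <- if (nrow(spikes)) max(spikes$t_ms) / 1000 else window
  }
  n_win <- max(1L, floor(t_end / window + 1e-9))
  win <- pmin(floor(spikes$t_ms / 1000 / window) + 1L, n_win)
  out <- expand.grid(window = seq_len(n_win), group = groups)
  cnt <- matrix(0, nrow = n_win, ncol = length(groups),
                dimnames = list(NULL, groups))
  if (nrow(spikes)) {
    tb <- table(factor(win, levels = seq_len(n_win)),
                factor(membership[spikes$id], levels = groups))
    cnt <- cnt + unclass(tb)
  }
  out$rate <- as.vector(cnt) / window /
    rep(as.numeric(counts_by_group), each = n_win)
  out$t_mid <- (out$window - 0.5) * window
  out[, c("window", "t_mid", "group", "rate")]
}

#' Group-resolved mean connectivity
#'
#' For every ordered pair of groups (source g, target h) the mean number of
#' synapses per ordered neuron pair, `sum(A[h, g]) / (|h| * |g|)`. For a
#' single group this is the network mean `sum(A) / n^2` (the diagonal is
#' included in the denominator; autapses do not occur, so it contributes
#' zeros).
#'
#' @param a Integer synapse-count matrix, entry `a[i, j]` = synapses from
#'   presynaptic `j` to postsynaptic `i`.
#' @param assignment A [assign_groups()] result (or an integer membership
#'   vector).
#' @return A `G x G` matrix; rows are target groups, columns source groups.
#'   The group-size-weighted mean of all blocks (attribute `"overall"`)
#'   equals the whole-matrix mean.
#' @examples
#' a <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
#' group_connectivity(a, assign_groups(2, 1)) # 3/4
#' @export
group_connectivity <- function(a, assignment) {
  memb <- if (inherits(assignment, "group_assignment")) {
    assignment$membership
  } else {
    as.integer(assignment)
  }
  stopifnot(nrow(a) == ncol(a), length(memb) == nrow(a))
  groups <- sort(unique(memb))
  g <- length(groups)
  out <- matrix(NA_real_, g, g,
                dimnames = list(target = groups, source = groups))
  for (h in seq_len(g)) {
    for (s in seq_len(g)) {
      out[h, s] <- mean(a[memb == groups[h], memb == groups[s], drop = FALSE])
    }
  }
  attr(out, "overall") <- sum(a) / length(memb)^2
  out
}

#' Fit a sum of three exponential decays to a connectivity trace
#'
#' Models the relaxation-phase connectivity change as
#' `A1*exp(-t/tau1) + A2*exp(-t/tau2) + A3*exp(-t/tau3)` with positive,
#' ordered time constants and free amplitude signs (relaxation can
#' overshoot). Because multi-exponential fits are ill-conditioned, the fit
#' starts from a ladder of initializations: time-constant triples are taken
#' log-spaced over `tau_range` and the amplitudes solved linearly for each
#' triple; the best start is refined by Levenberg-Marquardt least squares on
#' (A, log tau). If the refinement fails for every retained start, the best
#' linear-solve estimate is returned with `converged = FALSE` and a warning
#' (never a silent wrong fit). Non-decaying (flat) traces are flagged
#' `degenerate` rather than extrapolated.
#'
#' @param time Sample times, s.
#' @param value Connectivity change at `time` (typically relative to the
#'   pre-stimulation baseline).
#' @param t0 Start of the relaxation phase; only samples with `time >= t0`
#'   are fitted, with the clock restarted at `t0`.
#' @param tau_range Range of candidate time constants for the start ladder, s.
#' @param n_grid Number of log-spaced grid points for the ladder.
#' @param tau_max Upper bound for the fitted time constants, s. A finite
#'   noisy trace carries no information about components much slower than
#'   its span — unbounded, such components absorb baseline noise and blow
#'   up the integral. The default caps tau at four times the data span;
#'   integrals of slower transients are attributed at that horizon.
#' @return An object of class `exp_fit`: `amplitudes`, `taus` (ascending),
#'   `i_g` (the integral `sum(A * tau)`), `residual` (RSS), `converged`,
#'   `degenerate`.
#' @examples
#' t <- 0:200
#' fit <- fit_triple_exponential(t, 0.5 * exp(-t / 5) + 0.2 * exp(-t / 50))
#' fit$i_g # close to 0.5*5 + 0.2*50 = 12.5
#' @export
fit_triple_exponential <- function(time, value, t0 = min(time),
                                   tau_range = c(1, 1e4), n_grid = 8,
                                   tau_max = NULL) {
  keep <- time >= t0
  x <- time[keep] - t0
  y <- value[keep]
  if (is.null(tau_max)) tau_max <- 4 * (max(x) - min(x))
  if (length(x) < 30) {
    stop("need at least 30 samples in the relaxation phase", call. = FALSE)
  }
  if (sd(y) < 1e-14 || sd(y) < 1e-9 * max(abs(y), 1e-300)) {
    warning("trace does not decay; fit flagged degenerate", call. = FALSE)
    return(structure(list(amplitudes = rep(NA_real_, 3),
                          taus = rep(NA_real_, 3), i_g = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          degenerate = TRUE),
                     class = "exp_fit"))
  }

  taus_grid <- exp(seq(log(tau_range[1]), log(min(tau_range[2], tau_max)),
                       length.out = n_grid))
  combos <- utils::combn(taus_grid, 3)
  starts <- list()
  for (k in seq_len(ncol(combos))) {
    tau <- combos[, k]
    basis <- exp(-outer(x, 1 / tau))
    sol <- tryCatch(lm.fit(basis, y), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol$coefficients)) next
    rss <- sum(sol$residuals^2)
    starts[[length(starts) + 1]] <- list(a = unname(sol$coefficients),
                                         tau = tau, rss = rss)
  }
  if (!length(starts)) stop("exponential fit failed to initialize",
                            call. = FALSE)
  starts <- starts[order(vapply(starts, `[[`, numeric(1), "rss"))]

  model <- function(p, x) {
    p[1] * exp(-x / exp(p[4])) + p[2] * exp(-x / exp(p[5])) +
      p[3] * exp(-x / exp(p[6]))
  }
  best <- NULL
  for (s in head(starts, 5)) {
    p0 <- c(s$a, log(s$tau))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) y - model(p, x),
                         lower = c(rep(-Inf, 3), rep(log(1e-3), 3)),
                         upper = c(rep(Inf, 3), rep(log(tau_max), 3)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(p = fit$par, rss = rss, ok = fit$info %in% 1:4)
    }
  }

  if (is.null(best)) {
    warning("nonlinear refinement failed; returning linear-solve estimate",
            call. = FALSE)
    s <- starts[[1]]
    amp <- s$a
    tau <- s$tau
    rss <- s$rss
    converged <- FALSE
  } else {
    amp <- best$p[1:3]
    tau <- exp(best$p[4:6])
    rss <- best$rss
    converged <- isTRUE(best$ok)
  }
  ord <- order(tau)
  structure(list(amplitudes = amp[ord], taus = tau[ord],
                 i_g = sum(amp * tau), residual = rss,
                 converged = converged, degenerate = FALSE),
            class = "exp_fit")
}

#' Connectivity time integral
#'
#' The integral of the fitted multi-exponential connectivity change over
#' `[0, Inf)`: `sum(A_k * tau_k)`. This extrapolates transients that outlive
#' the simulated relaxation window and is the accumulated-outcome measure
#' used to compare stimulation protocols.
#'
#' @param fit An `exp_fit` object (see [fit_triple_exponential()]), or a
#'   numeric vector of amplitudes.
#' @param taus Time constants, required when `fit` is a numeric vector.
#' @return The integral, connectivity times seconds.
#' @examples
#' connectivity_integral(c(0.5, 0.2, 0), c(5, 50, 1)) # 12.5
#' @export
connectivity_integral <- function(fit, taus = NULL) {
  if (inherits(fit, "exp_fit")) {
    return(sum(fit$amplitudes * fit$taus))
  }
  stopifnot(!is.null(taus), length(fit) == length(taus))
  sum(fit * taus)
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("exp_fit: degenerate (non-decaying trace)\n")
    return(invisible(x))
  }
  cat(sprintf("exp_fit%s: I_G = %.4g\n",
              if (x$converged) "" else " (NOT converged)", x$i_g))
  for (k in 1:3) {
    cat(sprintf("  A%d = %+.4g, tau%d = %.4g s\n", k, x$amplitudes[k], k,
                x$taus[k]))
  }
  cat(sprintf("  RSS = %.4g\n", x$residual))
  invisible(x)
}
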