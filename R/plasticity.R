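#' Synaptic element pools
#'
#' Per-neuron bookkeeping of synaptic elements. `z_pre`/`z_post` are the
#' continuous element counters driven by the growth rule; the integer number
#' of usable elements is `floor(z)`, split into unbound (`free_*`) elements
#' and elements bound in synapses (the column/row sums of the synapse-count
#' matrix). Networks start with no elements at all.
#'
#' @param n Number of excitatory neurons.
#' @return An object of class `element_pools`.
#' @export
element_pools <- function(n) {
  structure(list(z_pre = numeric(n), z_post = numeric(n),
                 free_pre = integer(n), free_post = integer(n)),
            class = "element_pools")
}

#' Update calcium traces
#'
#' Exact update of the intracellular calcium trace for piecewise-constant
#' spike input over one interval: exponential decay with time constant
#' `tau_ca`, plus `beta_ca` per spike fired in the interval. The trace is a
#' running estimate of the firing rate: at a steady rate it fluctuates
#' around `rate * beta_ca * tau_ca`.
#'
#' @param calcium Numeric vector of per-neuron calcium concentrations.
#' @param spikes Integer vector of spike counts in the interval.
#' @param dt Interval length, s.
#' @param plasticity A [plasticity_params()].
#' @return Updated calcium vector.
#' @examples
#' update_calcium(0.008, 0L, dt = 10) # decays to 0.008 * exp(-1)
#' @export
update_calcium <- function(calcium, spikes, dt,
                           plasticity = plasticity_params()) {
  stopifnot(dt > 0, length(spikes) == length(calcium), all(calcium >= 0))
  calcium * exp(-dt / plasticity$tau_ca) + plasticity$beta_ca * spikes
}

#' Grow or shrink synaptic element counters
#'
#' Advances the continuous counters by the linear homeostatic rule
#' `dz = nu * (1 - C / eps) * dt` (identically for presynaptic and
#' postsynaptic elements) and reconciles the integer element counts: counters
#' that crossed an integer upward yield new free elements; counters that fell
#' below the number of elements currently held (free + bound) yield a
#' deficit, to be consumed by [delete_elements()].
#'
#' @param pools An [element_pools()] object.
#' @param calcium Per-neuron calcium trace.
#' @param a Synapse-count matrix (postsynaptic rows, presynaptic columns);
#'   its column/row sums are the bound element counts.
#' @param dt Structural update interval, s.
#' @param plasticity A [plasticity_params()].
#' @return A list with the updated `pools` and a `demand` data.frame
#'   (columns `neuron`, `kind`, `new_free`, `deficit`).
#' @export
update_elements <- function(pools, calcium, a, dt = plasticity$dt_struct,
                            plasticity = plasticity_params()) {
  stopifnot(dt > 0)
  dz <- plasticity$nu * (1 - calcium / plasticity$eps) * dt
  bound <- list(pre = colSums(a), post = rowSums(a))
  demand <- NULL
  for (kind in c("pre", "post")) {
    zf <- paste0("z_", kind)
    ff <- paste0("free_", kind)
    z <- pmax(pools[[zf]] + dz, 0)
    avail <- floor(z)
    held <- pools[[ff]] + bound[[kind]]
    surplus <- pmax(avail - held, 0)
    deficit <- pmax(held - avail, 0)
    pools[[zf]] <- z
    pools[[ff]] <- as.integer(pools[[ff]] + surplus)
    demand <- rbind(demand,
                    data.frame(neuron = seq_along(z), kind = kind,
                               new_free = as.integer(surplus),
                               deficit = as.integer(deficit)))
  }
  list(pools = pools, demand = demand[demand$new_free > 0 |
                                        demand$deficit > 0, ])
}

#' Combine free elements into new synapses
#'
#' Free boutons are randomly paired with free spines of other neurons:
#' `min(total free boutons, total free spines)` pairings are attempted, each
#' drawing one bouton and one spine uniformly at random across neurons.
#' Self-pairings (autapses) are re-drawn; pairs of distinct neurons may form
#' multiple synapses (multapses). Each formed synapse moves one element per
#' side from free to bound.
#'
#' @param pools An [element_pools()] object.
#' @param a Synapse-count matrix to increment.
#' @return A list with updated `pools`, `a`, and `new` (data.frame of formed
#'   synapses, columns `pre`, `post`).
#' @export
pair_free_elements <- function(pools, a) {
  pre_own <- rep.int(seq_along(pools$free_pre), pools$free_pre)
  post_own <- rep.int(seq_along(pools$free_post), pools$free_post)
  attempts <- min(length(pre_own), length(post_own))
  new_pre <- new_post <- integer(0)
  stuck <- 0L
  t <- 0L
  while (t < attempts && stuck < 20L) {
    t <- t + 1L
    ia <- sample.int(length(pre_own), 1)
    ib <- sample.int(length(post_own), 1)
    tries <- 0L
    while (pre_own[ia] == post_own[ib] && tries < 10L) {
      ib <- sample.int(length(post_own), 1)
      ia <- sample.int(length(pre_own), 1)
      tries <- tries + 1L
    }
    if (pre_own[ia] == post_own[ib]) {
      stuck <- stuck + 1L
      next
    }
    stuck <- 0L
    j <- pre_own[ia]
    i <- post_own[ib]
    a[i, j] <- a[i, j] + 1L
    pools$free_pre[j] <- pools$free_pre[j] - 1L
    pools$free_post[i] <- pools$free_post[i] - 1L
    new_pre <- c(new_pre, j)
    new_post <- c(new_post, i)
    pre_own <- pre_own[-ia]
    post_own <- post_own[-ib]
  }
  list(pools = pools, a = a, new = data.frame(pre = new_pre, post = new_post))
}

#' Remove elements to satisfy deficits
#'
#' Each deficit first consumes the neuron's free elements of that kind; any
#' remainder breaks synapses chosen uniformly at random among the neuron's
#' bound elements (so a multapse loses contacts in proportion to its
#' multiplicity). The partner of every broken synapse gets its element back
#' as a free element. If a deficit exceeds free + bound, the counter is
#' clamped at zero and the run flagged — the signature of a runaway
#' parameterization.
#'
#' @param pools An [element_pools()] object.
#' @param a Synapse-count matrix to decrement.
#' @param deficits The `demand` data.frame from [update_elements()].
#' @return A list with updated `pools`, `a`, `freed` (data.frame of freed
#'   counterpart elements: `neuron`, `kind`) and `clamped` (logical).
#' @export
delete_elements <- function(pools, a, deficits) {
  freed_n <- integer(0)
  freed_k <- character(0)
  clamped <- FALSE
  rows <- deficits[deficits$deficit > 0, , drop = FALSE]
  for (r in seq_len(nrow(rows))) {
    n <- rows$neuron[r]
    kind <- rows$kind[r]
    need <- rows$deficit[r]
    ff <- paste0("free_", kind)
    take <- min(need, pools[[ff]][n])
    pools[[ff]][n] <- pools[[ff]][n] - take
    need <- need - take
    while (need > 0) {
      partners <- if (kind == "pre") a[, n] else a[n, ]
      bound <- sum(partners)
      if (bound == 0) {
        clamped <- TRUE
        zf <- paste0("z_", kind)
        pools[[zf]][n] <- 0
        warning("element deficit exceeded free + bound; counter clamped at 0",
                call. = FALSE)
        break
      }
      p <- sample.int(length(partners), 1, prob = partners)
      if (kind == "pre") {
        a[p, n] <- a[p, n] - 1L
        pools$free_post[p] <- pools$free_post[p] + 1L
        freed_n <- c(freed_n, p)
        freed_k <- c(freed_k, "post")
      } else {
        a[n, p] <- a[n, p] - 1L
        pools$free_pre[p] <- pools$free_pre[p] + 1L
        freed_n <- c(freed_n, p)
        freed_k <- c(freed_k, "pre")
      }
      need <- need - 1
    }
  }
  list(pools = pools, a = a,
       freed = data.frame(neuron = freed_n, kind = freed_k),
       clamped = clamped)
}
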