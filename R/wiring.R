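#' Build the static (inhibition-involving) wiring of the network
#'
#' Populates the three static blocks — E to I, I to E, and I to I — either as
#' independent Bernoulli draws per ordered pair (the full-scale rule) or with
#' a fixed in-degree per target neuron, drawn with replacement (the
#' down-scaled rule; see [network_preset()]). Self-connections are never
#' drawn. The E-to-E block is left empty: those synapses are grown by the
#' structural-plasticity rule.
#'
#' The result is stored source-major (one flat target list plus an offset
#' per source neuron), the layout the simulation core walks when a spike is
#' propagated. Neurons are numbered 1..n_e (excitatory) and
#' n_e+1..n_e+n_i (inhibitory).
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed; the wiring is reproducible from it.
#' @return An object of class `static_wiring` with elements `src_ptr`
#'   (0-based offsets, length n_e+n_i+1), `tgt` (0-based target ids) and
#'   `counts` (synapse count per block).
#' @examples
#' w <- build_static_wiring(network_config(n_e = 20, n_i = 5), seed = 1)
#' w$counts
#' @export
build_static_wiring <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  n_e <- config$n_e
  n_i <- config$n_i
  n <- n_e + n_i

  # per-source target lists, global 0-based ids
  tgts <- vector("list", n)

  if (config$wiring == "bernoulli") {
    # Bernoulli(Gamma) per ordered pair == per source, Binomial(n_targets)
    # many targets sampled without replacement
    if (n_i > 0) {
      for (j in seq_len(n_e)) {  # E -> I
        k <- rbinom(1, n_i, config$gamma_ei)
        tgts[[j]] <- if (k > 0) n_e + sample.int(n_i, k) - 1L else integer(0)
      }
      for (jj in seq_len(n_i)) { # I -> E and I -> I (no autapses)
        k_e <- rbinom(1, n_e, config$gamma_ie)
        e_t <- if (k_e > 0) sample.int(n_e, k_e) - 1L else integer(0)
        k_i <- rbinom(1, n_i - 1, config$gamma_ii)
        i_t <- if (k_i > 0) {
          cand <- sample.int(n_i - 1, k_i)          # 1..n_i-1
          cand <- ifelse(cand >= jj, cand + 1L, cand) # skip self
          n_e + cand - 1L
        } else integer(0)
        tgts[[n_e + jj]] <- c(e_t, i_t)
      }
    }
  } else {
    # fixed in-degree per target, drawn with replacement (static multapses)
    src_of <- function(k, n_src, exclude = 0L) {
      s <- sample.int(n_src - (exclude > 0), k, replace = TRUE)
      if (exclude > 0) s <- ifelse(s >= exclude, s + 1L, s)
      s
    }
    edges_src <- integer(0)
    edges_tgt <- integer(0)
    if (n_i > 0) {
      for (ii in seq_len(n_i)) {   # E inputs of I neuron ii
        s <- src_of(config$k_ei, n_e)
        edges_src <- c(edges_src, s - 1L)
        edges_tgt <- c(edges_tgt, rep(n_e + ii - 1L, length(s)))
      }
      for (i in seq_len(n_e)) {    # I inputs of E neuron i
        s <- src_of(config$k_ie, n_i)
        edges_src <- c(edges_src, n_e + s - 1L)
        edges_tgt <- c(edges_tgt, rep(i - 1L, length(s)))
      }
      for (ii in seq_len(n_i)) {   # I inputs of I neuron ii, no autapses
        s <- src_of(config$k_ii, n_i, exclude = ii)
        edges_src <- c(edges_src, n_e + s - 1L)
        edges_tgt <- c(edges_tgt, rep(n_e + ii - 1L, length(s)))
      }
    }
    ord <- order(edges_src)
    by_src <- split(edges_tgt[ord], factor(edges_src[ord], levels = 0:(n - 1)))
    tgts <- unname(by_src)
  }

  len <- vapply(tgts, length, integer(1))
  tgt <- as.integer(unlist(tgts, use.names = FALSE))
  src_ptr <- as.integer(c(0L, cumsum(len)))

  src_is_e <- rep(c(TRUE, FALSE), c(n_e, n_i))[rep.int(seq_len(n), len)]
  tgt_is_e <- tgt < n_e
  counts <- c(e_to_i = sum(src_is_e & !tgt_is_e),
              i_to_e = sum(!src_is_e & tgt_is_e),
              i_to_i = sum(!src_is_e & !tgt_is_e))

  structure(list(n_e = n_e, n_i = n_i, src_ptr = src_ptr, tgt = tgt,
                 counts = counts, wiring = config$wiring),
            class = "static_wiring")
}

#' @export
print.static_wiring <- function(x, ...) {
  cat(sprintf("static wiring (%s): %d E->I, %d I->E, %d I->I synapses\n",
              x$wiring, x$counts["e_to_i"], x$counts["i_to_e"],
              x$counts["i_to_i"]))
  invisible(x)
}
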