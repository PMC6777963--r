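# Plain-text output of simulation records.

#' Write a spike record
#'
#' Two-column whitespace-separated text (neuron id, spike time in ms),
#' sorted by time.
#'
#' @param spikes data.frame with columns `id` and `t_ms`.
#' @param path Output file.
#' @export
write_spikes <- function(spikes, path) {
  sp <- spikes[order(spikes$t_ms), c("id", "t_ms")]
  write.table(sp, path, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a spike record written by [write_spikes()]
#' @param path Input file.
#' @return data.frame with columns `id`, `t_ms`.
#' @export
read_spikes <- function(path) {
  read.table(path, header = TRUE, colClasses = c("integer", "numeric"))
}

#' Write a connectivity matrix as sparse triplets
#'
#' Text columns `i` (postsynaptic), `j` (presynaptic), `count`; only nonzero
#' entries are written.
#'
#' @param a Integer synapse-count matrix.
#' @param path Output file.
#' @export
write_connectivity <- function(a, path) {
  nz <- which(a != 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1], j = nz[, 2], count = a[nz])
  df <- df[order(df$j, df$i), ]
  attr(df, "n") <- nrow(a)
  write.table(rbind(c(nrow(a), ncol(a), NA)), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  suppressWarnings(write.table(df, path, quote = FALSE, row.names = FALSE,
                               col.names = TRUE, append = TRUE))
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#' @param path Input file.
#' @return Integer matrix.
#' @export
read_connectivity <- function(path) {
  dims <- scan(path, nlines = 1, quiet = TRUE)
  df <- read.table(path, header = TRUE, skip = 1)
  a <- matrix(0L, dims[1], dims[2])
  a[cbind(df$i, df$j)] <- as.integer(df$count)
  a
}

#' Write a connectivity/rate trace table
#'
#' Columnar whitespace-separated text with a commented metadata header
#' (label and seed if provided).
#'
#' @param trace data.frame (e.g. the `trace` element of an experiment).
#' @param path Output file.
#' @param label Optional run label written to the header.
#' @param seed Optional seed written to the header.
#' @export
write_trace <- function(trace, path, label = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(label)) writeLines(sprintf("# run: %s", label), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  write.table(trace, con, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace table written by [write_trace()]
#' @param path Input file.
#' @return data.frame.
#' @export
read_trace <- function(path) {
  read.table(path, header = TRUE, comment.char = "#")
}

#' Save / load a grown-network checkpoint
#'
#' Checkpoints hold the complete simulator state at a phase boundary, so
#' stimulation protocols can be re-run without repeating the growth period.
#'
#' @param grown A `grown_network`.
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(grown, path) {
  stopifnot(inherits(grown, "grown_network"))
  saveRDS(grown, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  grown <- readRDS(path)
  stopifnot(inherits(grown, "grown_network"))
  grown
}
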