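# Disjoint marked representation of binned ensemble spiking.
#
# Each non-empty simultaneous-spiking pattern of C neurons is one "mark",
# indexed by the little-endian binary coding: neuron c contributes 2^(c-1).
# Pattern (1,1,1,0,0) is mark 7; every pattern including neuron 5 (C = 5)
# has an index in 16..31.

#' Binned ensemble spiking data
#'
#' Container for binary binned spiking of an ensemble of neurons. Bins are
#' half-open intervals `[k*bin_size, (k+1)*bin_size)`; a bin holds at most one
#' spike per neuron. Counts greater than one are clipped to one with a
#' warning, since the marked point-process model is binary per bin.
#'
#' @param counts integer/numeric matrix, neurons in rows, time bins in
#'   columns; entries are spike counts per bin.
#' @param bin_size bin width in seconds.
#' @param neuron_ids optional character labels, one per neuron.
#' @return An object of class `spike_ensemble` with elements `counts`
#'   (binary C x T matrix), `bin_size`, `neuron_ids`, and `n_clipped`, the
#'   number of entries clipped at ingestion.
#' @examples
#' sp <- spike_ensemble(matrix(rbinom(50, 1, 0.2), 5), bin_size = 0.01)
#' sp
#' @export
spike_ensemble <- function(counts, bin_size, neuron_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) < 2L) stop("need at least 2 neurons")
  if (ncol(counts) < 1L) stop("need at least 1 time bin")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("'bin_size' must be a positive scalar (seconds)")
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be non-negative")
  n_clipped <- sum(counts > 1L)
  if (n_clipped > 0L) {
    warning(sprintf("%d bins held more than one spike; clipped to 1", n_clipped))
    counts[counts > 1L] <- 1L
  }
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(counts)))
  rownames(counts) <- neuron_ids
  structure(list(counts = counts, bin_size = bin_size,
                 neuron_ids = neuron_ids, n_clipped = n_clipped),
            class = "spike_ensemble")
}

#' @export
print.spike_ensemble <- function(x, ...) {
  cat(sprintf("Binned ensemble spiking: %d neurons x %d bins (bin %g s)\n",
              nrow(x$counts), ncol(x$counts), x$bin_size))
  cat(sprintf("  total spikes: %d; clipped at ingestion: %d\n",
              sum(x$counts), x$n_clipped))
  invisible(x)
}

#' Encode a simultaneous-spiking pattern as a mark index
#'
#' Little-endian binary coding over the neuron index: neuron c contributes
#' `2^(c-1)`, so pattern `(1,1,1,0,0)` encodes to mark 7 and the all-zero
#' pattern to 0 (the no-event reference category).
#'
#' @param pattern binary vector of length C.
#' @return Integer mark index in `0..2^C-1`.
#' @examples
#' encode_pattern(c(1, 1, 1, 0, 0)) # 7
#' @seealso [decode_mark()], [mark_order()]
#' @export
encode_pattern <- function(pattern) {
  pattern <- as.integer(pattern)
  if (anyNA(pattern) || any(pattern < 0L | pattern > 1L))
    stop("pattern entries must be 0 or 1")
  C <- length(pattern)
  if (C < 1L || C > 30L) stop("pattern length must be in 1..30")
  sum(pattern * 2^(seq_len(C) - 1L))
}

#' Decode a mark index into its spiking pattern
#'
#' @param m mark index in `0..2^C-1`.
#' @param C number of neurons.
#' @return Binary vector of length C; `encode_pattern(decode_mark(m, C)) == m`.
#' @export
decode_mark <- function(m, C) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 0L || m > 2^C - 1)
    stop("mark index out of range 0..2^C-1")
  as.integer(intToBits(m))[seq_len(C)]
}

# vectorised population count over non-negative integers
popcount <- function(m) {
  m <- as.integer(m)
  r <- integer(length(m))
  while (any(m > 0L)) {
    r <- r + m %% 2L
    m <- m %/% 2L
  }
  r
}

#' Order of a mark (number of neurons spiking)
#'
#' @param m vector of mark indices, each at least 1.
#' @return Integer vector: the number of set bits of each index.
#' @examples
#' mark_order(c(7, 16, 31)) # 3 1 5
#' @export
mark_order <- function(m) {
  m <- as.integer(m)
  if (anyNA(m) || any(m < 1L))
    stop("mark indices must be >= 1 (the no-event category has no order)")
  popcount(m)
}

#' Enumerate all marks of a given order
#'
#' Returns the mark set of order r for a C-neuron ensemble: all indices whose
#' binary pattern has exactly r set bits, in ascending order. Its size is
#' `choose(C, r)`, the degrees of freedom of the rth-order coordination test.
#'
#' @param C number of neurons (at most 20; larger ensembles require
#'   event-driven counting of observed patterns only, see [mark_space()]).
#' @param r event order, `1 <= r <= C`.
#' @return Ascending integer vector of `choose(C, r)` mark indices.
#' @examples
#' order_marks(5, 3) # 10 marks, the df of the 3rd-order test for C = 5
#' @export
order_marks <- function(C, r) {
  if (C < 1L || C > 20L) stop("full mark enumeration is limited to C <= 20")
  if (r < 1L || r > C) stop("'r' must be in 1..C")
  m <- seq_len(2^C - 1L)
  m[popcount(m) == r]
}

#' Build the mark space and marked sequence from binned spiking
#'
#' Tallies every observed non-zero simultaneous-spiking pattern and retains
#' the "reliable interactions": marks occurring strictly more than `N_thr`
#' times. Bins whose observed pattern is pruned are recoded as no-event for
#' likelihood purposes (their rates are treated as negligible) but remain
#' flagged, so the original ground process is preserved. Counting is
#' event-driven (only observed patterns are tallied), so large ensembles do
#' not materialize all `2^C - 1` marks.
#'
#' @param x a [spike_ensemble].
#' @param N_thr non-negative pruning threshold; a mark is reliable when its
#'   event count exceeds `N_thr`.
#' @return An object of class `mark_space` with elements:
#'   `n_neurons`, `full_size` (`2^C - 1`), `reliable` (ascending mark
#'   indices), `order_of` (order of each reliable mark), `counts_per_mark`
#'   (named counts of every observed mark), `marks` (length-T sequence with
#'   values in `{0} U reliable`), `ground` (binary any-event indicator of the
#'   original data), `pruned_bins` (logical), `bin_size`, `neuron_ids`.
#' @examples
#' sp <- spike_ensemble(matrix(rbinom(60, 1, 0.3), 3), bin_size = 0.005)
#' ms <- mark_space(sp, N_thr = 1)
#' ms
#' @export
mark_space <- function(x, N_thr = 1L) {
  stopifnot(inherits(x, "spike_ensemble"))
  if (N_thr < 0) stop("'N_thr' must be >= 0")
  C <- nrow(x$counts)
  weights <- 2^(seq_len(C) - 1L)
  seq_all <- as.integer(drop(weights %*% x$counts))
  observed <- seq_all[seq_all > 0L]
  counts <- table(observed)
  counts_per_mark <- as.integer(counts)
  names(counts_per_mark) <- names(counts)
  reliable <- sort(as.integer(names(counts_per_mark)[counts_per_mark > N_thr]))
  pruned <- seq_all > 0L & !(seq_all %in% reliable)
  marks <- seq_all
  marks[pruned] <- 0L
  structure(list(
    n_neurons = C,
    full_size = 2^C - 1,
    reliable = reliable,
    order_of = if (length(reliable)) mark_order(reliable) else integer(0),
    counts_per_mark = counts_per_mark,
    N_thr = as.integer(N_thr),
    marks = marks,
    ground = as.integer(seq_all > 0L),
    pruned_bins = pruned,
    bin_size = x$bin_size,
    neuron_ids = x$neuron_ids
  ), class = "mark_space")
}

#' @export
print.mark_space <- function(x, ...) {
  cat(sprintf("Mark space: C = %d neurons, %d possible marks\n",
              x$n_neurons, x$full_size))
  cat(sprintf("  observed marks: %d; reliable (count > %d): %d\n",
              length(x$counts_per_mark), x$N_thr, length(x$reliable)))
  cat(sprintf("  events: %d; pruned bins recoded to no-event: %d\n",
              sum(x$ground), sum(x$pruned_bins)))
  if (length(x$reliable)) {
    tab <- table(factor(x$order_of, levels = seq_len(x$n_neurons)))
    cat("  reliable marks by order:",
        paste(sprintf("r=%s:%d", names(tab)[tab > 0], tab[tab > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recover one neuron's spike train from the marked sequence
#'
#' Sums the disjoint marked events over all marks whose pattern includes the
#' requested neuron. Equal to the original binary spike train wherever no
#' pruning occurred.
#'
#' @param ms a [mark_space].
#' @param c neuron index in `1..C`.
#' @return Binary integer vector over bins.
#' @export
recover_neuron_train <- function(ms, c) {
  stopifnot(inherits(ms, "mark_space"))
  if (c < 1L || c > ms$n_neurons) stop("neuron index out of range")
  as.integer(bitwAnd(ms$marks, 2^(c - 1L)) > 0L)
}

#' Effective integration window of the forgetting-factor estimator
#'
#' The exponentially weighted window log-likelihood with forgetting factor
#' `beta` and window length `W` integrates, in effect, about `W / (1 - beta)`
#' bins of data; e.g. (W, beta) = (10, 0.975) gives 400 bins.
#'
#' @param W window length in bins.
#' @param beta forgetting factor in `[0, 1)`.
#' @return Effective number of bins `W / (1 - beta)`.
#' @export
effective_window <- function(W, beta) {
  stopifnot(W >= 1, beta >= 0, beta < 1)
  W / (1 - beta)
}

#' Event-rate threshold implied by a pruning count
#'
#' Pruning marks with at most `N_thr` events over a recording of `duration`
#' seconds treats as negligible all simultaneous-spiking events with average
#' rate below `N_thr / duration` Hz (e.g. 15 events over 1000 s = 0.015 Hz).
#'
#' @param N_thr pruning threshold (event count).
#' @param duration recording duration in seconds.
#' @return Rate threshold in Hz.
#' @export
negligible_rate <- function(N_thr, duration) {
  stopifnot(N_thr >= 0, duration > 0)
  N_thr / duration
}
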