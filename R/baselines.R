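# Single-trial comparison measures: smoothed pairwise Pearson correlation,
# spiking regularity (coefficient of variation of inter-spike intervals),
# and average mark-CIF differences from conditional independence.

new_windowed_metric <- function(window_start, value, ci_low, ci_high,
                                metric, bin_size) {
  structure(data.frame(window_start = window_start, value = value,
                       ci_low = ci_low, ci_high = ci_high),
            metric = metric, bin_size = bin_size,
            class = c("windowed_metric", "data.frame"))
}

#' @export
print.windowed_metric <- function(x, ...) {
  cat(sprintf("%s over %d non-overlapping windows\n",
              attr(x, "metric"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Plot a windowed baseline metric with its confidence band
#'
#' @param x a `windowed_metric`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.windowed_metric <- function(x, ...) {
  t0 <- x$window_start * attr(x, "bin_size")
  graphics::plot(t0, x$value, type = "l", xlab = "time (s)",
                 ylab = attr(x, "metric"),
                 ylim = range(c(x$ci_low, x$ci_high, x$value), na.rm = TRUE),
                 ...)
  graphics::lines(t0, x$ci_low, lty = 2, col = "grey50")
  graphics::lines(t0, x$ci_high, lty = 2, col = "grey50")
  invisible(x)
}

gauss_smooth <- function(y, sd_bins) {
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- stats::dnorm(-half:half, sd = sd_bins)
  kern <- kern / sum(kern)
  out <- stats::filter(c(rep(0, half), y, rep(0, half)), kern, sides = 2L)
  as.numeric(out[(half + 1L):(half + length(y))])
}

#' Average pairwise correlation of smoothed spike trains
#'
#' Each train is smoothed with a Gaussian kernel, and the Pearson
#' correlation is averaged over all neuron pairs within non-overlapping
#' windows; the 95% confidence band is computed on the Fisher z-scale
#' across pairs. Zero-variance pairs within a window are excluded.
#'
#' @param x a [spike_ensemble].
#' @param kernel_sd Gaussian kernel standard deviation in bins.
#' @param window window length in bins.
#' @return A `windowed_metric` data frame.
#' @export
smoothed_pearson <- function(x, kernel_sd = 5, window = 200L) {
  stopifnot(inherits(x, "spike_ensemble"), kernel_sd > 0, window >= 2L)
  S <- t(apply(x$counts, 1L, gauss_smooth, sd_bins = kernel_sd))
  T_ <- ncol(S)
  K <- T_ %/% window
  C <- nrow(S)
  pairs <- utils::combn(C, 2L)
  val <- lo <- hi <- rep(NA_real_, K)
  n_excluded <- 0L
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * window + 1L):(k * window)
    Z <- S[, idx, drop = FALSE]
    sds <- apply(Z, 1L, stats::sd)
    rs <- apply(pairs, 2L, function(pq) {
      if (sds[pq[1L]] == 0 || sds[pq[2L]] == 0) return(NA_real_)
      stats::cor(Z[pq[1L], ], Z[pq[2L], ])
    })
    n_excluded <- n_excluded + sum(is.na(rs))
    rs <- rs[!is.na(rs)]
    if (!length(rs)) next
    z <- atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12))
    zm <- mean(z)
    zse <- if (length(z) > 1L) stats::sd(z) / sqrt(length(z)) else 0
    val[k] <- tanh(zm)
    lo[k] <- tanh(zm - 1.96 * zse)
    hi[k] <- tanh(zm + 1.96 * zse)
  }
  out <- new_windowed_metric((seq_len(K) - 1L) * window, val, lo, hi,
                             "average pairwise correlation (smoothed)",
                             x$bin_size)
  attr(out, "n_pairs_excluded") <- n_excluded
  out
}

#' Spiking regularity: coefficient of variation of inter-spike intervals
#'
#' Per neuron and non-overlapping window, the ratio of the standard
#' deviation to the mean of the inter-spike intervals (in bins); averaged
#' across neurons with a +/- 2 SEM band. A value near 1 indicates
#' Poisson-like spiking; below 1, regular (globally coordinated) spiking;
#' above 1, bursty self-exciting dynamics. Neurons with fewer than two
#' intervals in a window are skipped there.
#'
#' @param x a [spike_ensemble].
#' @param window window length in bins.
#' @return A `windowed_metric` data frame.
#' @export
spiking_regularity <- function(x, window = 200L) {
  stopifnot(inherits(x, "spike_ensemble"), window >= 2L)
  T_ <- ncol(x$counts)
  K <- T_ %/% window
  val <- lo <- hi <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * window + 1L):(k * window)
    cvs <- apply(x$counts[, idx, drop = FALSE], 1L, function(y) {
      isi <- diff(which(y == 1L))
      if (length(isi) < 2L) return(NA_real_)
      stats::sd(isi) / mean(isi)
    })
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) next
    val[k] <- mean(cvs)
    sem <- if (length(cvs) > 1L) stats::sd(cvs) / sqrt(length(cvs)) else 0
    lo[k] <- val[k] - 2 * sem
    hi[k] <- val[k] + 2 * sem
  }
  new_windowed_metric((seq_len(K) - 1L) * window, val, lo, hi,
                      "spiking regularity (CV of ISIs)", x$bin_size)
}

#' Average rth-order mark-CIF difference from conditional independence
#'
#' Per bin, the difference between each rth-order mark's fitted event
#' probability and the probability of the same pattern under conditional
#' independence of its neurons (composed from the model's per-neuron
#' marginals), averaged over the rth-order marks; summarized per reporting
#' window with a +/- 2 SEM band across marks.
#'
#' @param object an [mkpp_fit].
#' @param r event order.
#' @param window reporting window in bins.
#' @return A `windowed_metric` data frame; empty (zero rows kept, all NA)
#'   with a message when no reliable mark has order r.
#' @export
mark_cif_difference <- function(object, r = 3L, window = 200L) {
  stopifnot(inherits(object, "mkpp_fit"))
  ms <- object$mark_space
  pos <- which(ms$order_of == r)
  T_ <- length(object$o)
  K <- T_ %/% window
  if (!length(pos)) {
    message("no reliable marks of order ", r)
    return(new_windowed_metric((seq_len(K) - 1L) * window,
                               rep(NA_real_, K), rep(NA_real_, K),
                               rep(NA_real_, K),
                               sprintf("order-%d mark-CIF difference", r),
                               ms$bin_size))
  }
  C <- ms$n_neurons
  patt <- vapply(ms$reliable, decode_mark, integer(C), C = C)
  P <- predict(object, type = "prob")[, -1L, drop = FALSE]
  Pi <- pmin(pmax(P %*% t(patt), 1e-12), 1 - 1e-12)
  # independence probability of the exact pattern, on the model's event scale
  logq <- matrix(0, T_, length(pos))
  for (j in seq_along(pos)) {
    in_m <- patt[, pos[j]] == 1L
    logq[, j] <- rowSums(log(Pi[, in_m, drop = FALSE])) +
      rowSums(log1p(-Pi[, !in_m, drop = FALSE]))
  }
  diffs <- P[, pos, drop = FALSE] - exp(logq)
  val <- lo <- hi <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * window + 1L):(k * window)
    per_mark <- colMeans(diffs[idx, , drop = FALSE])
    val[k] <- mean(per_mark)
    sem <- if (length(per_mark) > 1L)
      stats::sd(per_mark) / sqrt(length(per_mark)) else 0
    lo[k] <- val[k] - 2 * sem
    hi[k] <- val[k] + 2 * sem
  }
  new_windowed_metric((seq_len(K) - 1L) * window, val, lo, hi,
                      sprintf("order-%d mark-CIF difference", r), ms$bin_size)
}
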