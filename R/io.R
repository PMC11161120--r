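# Delimited-text readers and writers for binned spike data, marked
# sequences, fitted parameters and test results, plus a run manifest.
# Time bins are half-open [k*bin_size, (k+1)*bin_size), 0-based in files'
# time columns and 1-based in window/bin reports.

#' Write / read a binary spike matrix as delimited text
#'
#' Tab-separated, neurons in rows: first column `neuron` (the label),
#' remaining columns the 0/1 bins. The bin size is stored in a YAML sidecar
#' (`<file>.yaml`). An RDS-based container (`write_spike_rds` /
#' `read_spike_rds`) is available for large data created at run time.
#'
#' @param x a [spike_ensemble].
#' @param file output path.
#' @param sidecar sidecar path holding `bin_size` (default `<file>.yaml`).
#' @return `file`, invisibly (writers); a [spike_ensemble] (readers).
#' @export
write_spike_matrix <- function(x, file, sidecar = paste0(file, ".yaml")) {
  stopifnot(inherits(x, "spike_ensemble"))
  df <- data.frame(neuron = x$neuron_ids, x$counts, check.names = FALSE)
  colnames(df) <- c("neuron", paste0("t", seq_len(ncol(x$counts))))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(bin_size = x$bin_size,
                        neuron_ids = as.character(x$neuron_ids)), sidecar)
  invisible(file)
}

#' @rdname write_spike_matrix
#' @param bin_size bin width in seconds; overrides the sidecar when given.
#' @export
read_spike_matrix <- function(file, bin_size = NULL,
                              sidecar = paste0(file, ".yaml")) {
  df <- utils::read.delim(file, check.names = FALSE)
  if (!"neuron" %in% colnames(df))
    stop(sprintf("%s: missing 'neuron' column (line 1)", file))
  counts <- as.matrix(df[, setdiff(colnames(df), "neuron"), drop = FALSE])
  dimnames(counts) <- NULL
  if (is.null(bin_size)) {
    if (!file.exists(sidecar))
      stop("bin_size not given and sidecar config not found: ", sidecar)
    bin_size <- yaml::read_yaml(sidecar)$bin_size
  }
  spike_ensemble(counts, bin_size, neuron_ids = as.character(df$neuron))
}

#' @rdname write_spike_matrix
#' @export
write_spike_rds <- function(x, file) {
  stopifnot(inherits(x, "spike_ensemble"))
  saveRDS(x, file)
  invisible(file)
}

#' @rdname write_spike_matrix
#' @export
read_spike_rds <- function(file) {
  x <- readRDS(file)
  if (!inherits(x, "spike_ensemble")) stop("not a spike_ensemble container")
  x
}

#' Read / write an event list (neuron id, spike time)
#'
#' Two-column tab-separated text: `neuron` and `time` (seconds). Reading
#' bins events into half-open intervals `[k*bin_size, (k+1)*bin_size)`;
#' multiple spikes of one neuron in a bin are clipped to one (reported by
#' [spike_ensemble()]).
#'
#' @param file path to the event list.
#' @param bin_size bin width in seconds.
#' @param duration recording duration in seconds (default: last spike time
#'   rounded up to a whole bin).
#' @return A [spike_ensemble].
#' @export
read_event_list <- function(file, bin_size, duration = NULL) {
  df <- utils::read.delim(file)
  need <- c("neuron", "time")
  if (!all(need %in% colnames(df)))
    stop(sprintf("%s: expected columns 'neuron' and 'time' (line 1)", file))
  bad <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad))
    stop(sprintf("%s: invalid spike time at line %d", file, bad[1L] + 1L))
  ids <- sort(unique(as.character(df$neuron)))
  if (is.null(duration)) duration <- (floor(max(df$time) / bin_size) + 1L) * bin_size
  T_ <- max(1L, ceiling(duration / bin_size - 1e-9))
  counts <- matrix(0L, length(ids), T_, dimnames = list(ids, NULL))
  # half-open binning with a guard against decimal-text rounding error
  bin <- floor(df$time / bin_size + 1e-9) + 1L
  keep <- bin <= T_
  for (i in which(keep)) {
    ci <- match(as.character(df$neuron[i]), ids)
    counts[ci, bin[i]] <- counts[ci, bin[i]] + 1L
  }
  spike_ensemble(counts, bin_size)
}

#' @rdname read_event_list
#' @param x a [spike_ensemble] to write.
#' @export
write_event_list <- function(x, file) {
  stopifnot(inherits(x, "spike_ensemble"))
  ev <- which(x$counts == 1L, arr.ind = TRUE)
  ev <- ev[order(ev[, 2L], ev[, 1L]), , drop = FALSE]
  df <- data.frame(neuron = x$neuron_ids[ev[, 1L]],
                   time = (ev[, 2L] - 1L) * x$bin_size)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the mark-space summary and marked sequence
#'
#' `write_mark_summary` writes one row per observed mark: index, pattern
#' string (neuron 1 leftmost), order, event count, and whether it is
#' reliable. `write_marked_sequence` writes the per-bin mark index.
#'
#' @param ms a [mark_space].
#' @param file output path.
#' @export
write_mark_summary <- function(ms, file) {
  stopifnot(inherits(ms, "mark_space"))
  m <- as.integer(names(ms$counts_per_mark))
  df <- data.frame(
    mark = m,
    pattern = vapply(m, function(mm)
      paste(decode_mark(mm, ms$n_neurons), collapse = ""), character(1)),
    order = mark_order(m),
    count = as.integer(ms$counts_per_mark),
    reliable = m %in% ms$reliable)
  df <- df[order(df$mark), ]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_mark_summary
#' @export
write_marked_sequence <- function(ms, file) {
  stopifnot(inherits(ms, "mark_space"))
  df <- data.frame(bin = seq_along(ms$marks), mark = ms$marks,
                   ground = ms$ground, pruned = as.integer(ms$pruned_bins))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize a fitted trajectory to columnar text
#'
#' One row per (window, parameter): window index, mark, parameter name
#' (`mu` or the covariate name), and value.
#'
#' @param object an [mkpp_fit].
#' @param file output path.
#' @export
write_params <- function(object, file) {
  stopifnot(inherits(object, "mkpp_fit"))
  marks <- object$mark_space$reliable
  rows <- vector("list", object$K)
  for (k in seq_len(object$K)) {
    df <- data.frame(window = k, mark = marks, parameter = "mu",
                     value = object$mu[, k])
    tt <- object$theta_traj[[k]]
    if (!is.null(tt) && nrow(tt$support)) {
      df <- rbind(df, data.frame(
        window = k, mark = marks[tt$support[, 1L]],
        parameter = colnames(object$X)[tt$support[, 2L]],
        value = tt$values))
    }
    rows[[k]] <- df
  }
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write coordination-test results as delimited text
#'
#' Columns: window, time_start_s, r, D, nu_hat, h, J, sum_gamma.
#'
#' @param ct a `coord_test`.
#' @param file output path.
#' @export
write_results <- function(ct, file) {
  stopifnot(inherits(ct, "coord_test"))
  df <- ct$results[, c("window", "time_start", "r", "D", "nu_hat", "h", "J",
                       "sum_gamma")]
  colnames(df)[2L] <- "time_start_s"
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and package version needed to reproduce
#' a run bit-identically.
#'
#' @param config named list of hyperparameters.
#' @param file output path (YAML).
#' @param seed the seed used.
#' @export
write_manifest <- function(config, file, seed = NA_integer_) {
  info <- list(
    package = "hocoord",
    version = as.character(utils::packageVersion("hocoord")),
    seed = seed,
    config = config)
  yaml::write_yaml(info, file)
  invisible(file)
}
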