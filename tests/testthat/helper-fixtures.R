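# Small in-code fixtures shared across test files.

# independent stationary ensemble, C neurons, per-bin rate, no history
sim_null <- function(C = 3, nbins = 1000, rate = 0.15, seed = 1,
                     bin_size = 0.001) {
  par <- neuron_params(rep(stats::qlogis(rate), C))
  simulate_ensemble(C, nbins, par, L = 1L, bin_size = bin_size, seed = seed)
}

# deterministic tiny spike matrix with known patterns
toy_spikes <- function() {
  counts <- matrix(0L, 3, 20)
  # neurons {1,2} spike together in 5 bins (mark 3)
  counts[1:2, c(2, 5, 9, 14, 18)] <- 1L
  # all three spike together once (mark 7)
  counts[1:3, 11] <- 1L
  # neuron 3 alone twice (mark 4)
  counts[3, c(4, 16)] <- 1L
  spike_ensemble(counts, bin_size = 0.01)
}

expect_no_error <- function(expr) testthat::expect_error(expr, NA)
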