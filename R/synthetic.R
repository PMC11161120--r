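# Ground-truth simulator for non-stationary marked point-process ensemble
# spiking. Per bin t the log-odds of mark m versus no event are
#   u_t(m) = mu(m) + x_t' theta(m) + gamma_t(m),
# one categorical outcome is drawn over {no event} U marks (which enforces
# the disjoint encoding exactly), and the lag buffer is updated.
#
# When mu(m) = sum_{c in m} a_c and theta(m) = sum_{c in m} b_c over the full
# mark space, the categorical distribution factorizes into independent
# Bernoulli neurons with logit a_c + b_c' x_t: the normalizer is
# prod_c (1 + exp(eta_c)). Exogenous offsets gamma_t(m) on selected marks
# then break conditional independence exactly for those patterns and nothing
# else, which is what the coordination tests are meant to detect.

#' Compose mark-level parameters from per-neuron terms
#'
#' Builds parameters over the full mark space with `mu(m) = sum_{c in m} a_c`
#' and `theta(m) = sum_{c in m} b[, c]`. Under this composition the simulated
#' neurons are conditionally independent given ensemble history; any
#' departure from independence must come from exogenous offsets.
#'
#' @param a numeric length-C vector of per-neuron baseline log-odds.
#' @param b optional `(C*L) x C` matrix of per-neuron history couplings in
#'   the lag-major covariate ordering of [history_covariates()]; the lag
#'   depth is inferred from its row count.
#' @return An [mkpp_params] over all `2^C - 1` marks.
#' @export
neuron_params <- function(a, b = NULL) {
  C <- length(a)
  marks <- seq_len(2^C - 1L)
  patt <- vapply(marks, decode_mark, integer(C), C = C)  # C x M
  mu <- drop(a %*% patt)
  theta <- NULL
  if (!is.null(b)) {
    b <- as.matrix(b)
    stopifnot(ncol(b) == C)
    theta <- b %*% patt
    rownames(theta) <- paste0("c", rep(seq_len(C), nrow(b) %/% C),
                              ".l", rep(seq_len(nrow(b) %/% C), each = C))
  }
  mkpp_params(mu, theta, marks = marks)
}

softmax_probs <- function(u) {
  mx <- max(0, u)
  e <- exp(u - mx)
  z <- exp(-mx) + sum(e)
  c(exp(-mx) / z, e / z)
}

#' Simulate non-stationary marked point-process ensemble spiking
#'
#' Draws one categorical outcome per bin over the no-event category and the
#' model's marks, with log-odds `mu(m) + x_t' theta(m) + gamma_t(m)` where
#' `x_t` holds the lag-1..L history of the simulated spiking itself. The
#' exogenous track `gamma` and all ground truth are returned alongside the
#' data. Fixed seeds give bit-identical output.
#'
#' @param C number of neurons.
#' @param nbins number of time bins.
#' @param params an [mkpp_params] (typically from [neuron_params()]); its
#'   marks may be any subset of `1..2^C-1`.
#' @param gamma NULL, or a numeric matrix with `nbins` rows whose column
#'   names are mark indices: per-bin exogenous log-odds offsets for the
#'   driven marks.
#' @param theta_gate optional length-`nbins` 0/1 vector multiplying the
#'   history couplings per bin (time-varying endogenous effects).
#' @param L lag depth of the simulator's history buffer.
#' @param bin_size bin width in seconds for the returned [spike_ensemble].
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param epochs optional data frame of labelled intervals carried through to
#'   the output.
#' @param track optional latent driver series carried through to the output.
#' @return Object of class `hoc_scenario`: `spikes` (a [spike_ensemble]),
#'   `marks_seq` (the drawn mark per bin), `gamma_true`, `epochs`, `track`,
#'   `params`, `seed`.
#' @export
simulate_ensemble <- function(C, nbins, params, gamma = NULL,
                              theta_gate = NULL, L = 5L, bin_size = 0.001,
                              seed = NULL, epochs = NULL, track = NULL) {
  stopifnot(inherits(params, "mkpp_params"), nbins >= 1L, C >= 2L)
  if (!is.null(seed)) set.seed(seed)
  marks <- params$marks
  Mg <- length(marks)
  if (any(marks < 1L) || any(marks > 2^C - 1L))
    stop("params$marks out of range for C neurons")
  patt <- vapply(marks, decode_mark, integer(C), C = C)  # C x Mg
  gm <- NULL
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != nbins) stop("gamma must have one row per bin")
    gcols <- match(as.integer(colnames(gamma)), marks)
    if (anyNA(gcols)) stop("gamma column names must be mark indices in the model")
    gm <- matrix(0, nbins, Mg)
    gm[, gcols] <- gamma
  }
  has_theta <- nrow(params$theta) > 0L && any(params$theta != 0)
  spikes <- matrix(0L, C, nbins)
  marks_seq <- integer(nbins)
  if (!has_theta) {
    # no feedback: sample bins in groups sharing the same offset row
    key <- if (is.null(gm)) rep("", nbins) else
      do.call(paste, c(as.data.frame(gm), sep = "\r"))
    for (grp in split(seq_len(nbins), key)) {
      u <- params$mu + if (is.null(gm)) 0 else gm[grp[1L], ]
      pr <- softmax_probs(u)
      o <- sample.int(Mg + 1L, length(grp), replace = TRUE, prob = pr) - 1L
      marks_seq[grp] <- ifelse(o == 0L, 0L, marks[pmax(o, 1L)])
      hit <- o > 0L
      if (any(hit)) spikes[, grp[hit]] <- patt[, o[hit], drop = FALSE]
    }
    # grouped sampling permutes the RNG stream relative to bin order but is
    # deterministic for a fixed seed
  } else {
    p <- C * L
    if (nrow(params$theta) != p)
      stop("params$theta must have C*L rows matching the simulator's lag depth")
    gate <- if (is.null(theta_gate)) rep(1, nbins) else theta_gate
    xbuf <- integer(p)  # lag-major: lag-1 block first
    for (t in seq_len(nbins)) {
      u <- params$mu
      if (!is.null(gm)) u <- u + gm[t, ]
      if (gate[t] != 0) {
        active <- which(xbuf == 1L)
        if (length(active))
          u <- u + gate[t] * colSums(params$theta[active, , drop = FALSE])
      }
      pr <- softmax_probs(u)
      o <- sample.int(Mg + 1L, 1L, prob = pr) - 1L
      newbin <- integer(C)
      if (o > 0L) {
        marks_seq[t] <- marks[o]
        newbin <- patt[, o]
        spikes[, t] <- newbin
      }
      if (L > 1L) xbuf[(C + 1L):p] <- xbuf[1L:(p - C)]
      xbuf[1L:C] <- newbin
    }
  }
  structure(list(
    spikes = spike_ensemble(spikes, bin_size),
    marks_seq = marks_seq,
    gamma_true = gamma,
    epochs = epochs,
    track = track,
    params = params,
    seed = seed
  ), class = "hoc_scenario")
}

#' @export
print.hoc_scenario <- function(x, ...) {
  cat(sprintf("Simulated ensemble spiking scenario: %d neurons x %d bins\n",
              nrow(x$spikes$counts), ncol(x$spikes$counts)))
  if (!is.null(x$gamma_true))
    cat(sprintf("  exogenously driven marks: %s\n",
                paste(colnames(x$gamma_true), collapse = ", ")))
  if (!is.null(x$epochs)) {
    cat("  epochs:\n")
    print(x$epochs, row.names = FALSE)
  }
  invisible(x)
}

# per-neuron baseline giving per-bin spiking probability ~ rate
baseline_logits <- function(C, rate) rep(stats::qlogis(rate), C)

#' Step-facilitation validation scenario
#'
#' Realizations of a C-neuron ensemble in which a step function exogenously
#' facilitates all 3rd-order simultaneous spiking during the second half of
#' each realization; the first half is exactly null (independent neurons,
#' no history couplings). Used to validate the limiting distributions of the
#' de-biased deviance difference under both hypotheses.
#'
#' @param n_realizations number of independent realizations.
#' @param nbins bins per realization.
#' @param C ensemble size.
#' @param rate per-neuron baseline spiking probability per bin. The default
#'   makes every 2nd- to 4th-order mark reliable over one realization while
#'   5th-order events stay below the pruning threshold, so pruning at
#'   N_thr = 1 excludes exactly the full-ensemble events.
#' @param amplitude step height on the log-odds of every 3rd-order mark.
#' @param bin_size seconds per bin.
#' @param seed base seed; realization i uses `seed + i - 1`.
#' @return List of `hoc_scenario` objects (length `n_realizations`).
#' @export
scenario_step <- function(n_realizations = 50L, nbins = 4000L, C = 5L,
                          rate = 0.175, amplitude = 1.5, bin_size = 0.001,
                          seed = 1L) {
  par <- neuron_params(baseline_logits(C, rate))
  k3 <- order_marks(C, 3L)
  half <- nbins %/% 2L
  gamma <- matrix(0, nbins, length(k3), dimnames = list(NULL, k3))
  if (half < nbins) gamma[(half + 1L):nbins, ] <- amplitude
  epochs <- data.frame(start = c(1L, half + 1L), end = c(half, nbins),
                       label = c("null", "facilitation"))
  lapply(seq_len(n_realizations), function(i)
    simulate_ensemble(C, nbins, par, gamma = gamma, L = 1L,
                      bin_size = bin_size, seed = seed + i - 1L,
                      epochs = epochs))
}

# hub-triggered co-excitation: the last neuron's spikes transiently
# (one bin) co-elevate the other neurons' spiking probabilities, so
# coincident events up to 4th order cluster in rare single-bin bursts.
# Couplings act per neuron: conditional independence given history is exact.
hub_couplings <- function(C, L, excite) {
  b <- matrix(0, C * L, C)
  b[C, seq_len(C - 1L)] <- excite  # lag-1 block: first C rows
  b
}

#' Square-wave scenario: exogenous 3rd-order, endogenous 4th-order events
#'
#' A square wave alternately facilitates and suppresses all 3rd-order
#' simultaneous spiking (four epochs of `half_period` bins), while 4th-order
#' events among neurons 1..4 arise endogenously throughout: spikes of the
#' background neuron (the hub, neuron 5) transiently co-excite neurons 1..4
#' at lag 1, so high-order coincidences among them cluster in rare,
#' single-bin bursts. The coupling acts per neuron, so conditional
#' independence given ensemble history holds exactly for the 4th-order
#' events: a history-dependent test should attribute them to endogenous
#' effects, while a history-independent test sees their marginal rate far
#' exceed the rate composed from the neurons' marginal rates.
#'
#' @param nbins total bins; the default half-period is `nbins / 4`.
#' @param half_period bins per facilitation/suppression epoch.
#' @param rate per-bin baseline spiking probability of neurons 1..4.
#' @param hub_rate per-bin spiking probability of the hub neuron.
#' @param excite lag-1 co-excitation (log-odds) that a hub spike adds to
#'   each of neurons 1..4.
#' @inheritParams scenario_step
#' @return A `hoc_scenario` with epoch labels and the exogenous truth.
#' @export
scenario_square_wave <- function(nbins = 16000L, C = 5L, rate = 0.1,
                                 hub_rate = 0.05, amplitude = 1.5,
                                 half_period = nbins %/% 4L,
                                 excite = 3.3, L = 5L,
                                 bin_size = 0.001, seed = 1L) {
  a <- c(rep(stats::qlogis(rate), C - 1L), stats::qlogis(hub_rate))
  b <- hub_couplings(C, L, excite)
  par <- neuron_params(a, b)
  k3 <- order_marks(C, 3L)
  phase <- ((seq_len(nbins) - 1L) %/% half_period) %% 2L  # 0 = facilitation
  gamma <- matrix(ifelse(phase == 0L, amplitude, -amplitude),
                  nbins, length(k3), dimnames = list(NULL, k3))
  n_ep <- ceiling(nbins / half_period)
  epochs <- data.frame(
    start = (seq_len(n_ep) - 1L) * half_period + 1L,
    end = pmin(seq_len(n_ep) * half_period, nbins),
    label = rep(c("facilitation", "suppression"), length.out = n_ep))
  simulate_ensemble(C, nbins, par, gamma = gamma, L = L,
                    bin_size = bin_size, seed = seed, epochs = epochs)
}

#' Autoregressive-drive scenario
#'
#' One realization of an AR(1) latent process exogenously drives 3rd-order
#' spiking (`gamma = gain * track` on every 3rd-order mark; facilitation is
#' most evident where the track exceeds `threshold`), while 4th-order events
#' are endogenously induced (lag-1 mutual excitation among neurons 1..4)
#' during the first and last thirds of the recording only.
#'
#' @param ar_coef AR(1) coefficient of the latent track.
#' @param noise_sd innovation standard deviation (stationary SD is
#'   `noise_sd / sqrt(1 - ar_coef^2)`, about 1 at the defaults).
#' @param gain log-odds per unit of the latent track.
#' @param threshold level above which facilitation epochs are labelled.
#' @inheritParams scenario_square_wave
#' @return A `hoc_scenario` with the latent `track`, exogenous truth, and
#'   epoch labels for both the endogenous 4th-order thirds and the
#'   above-threshold intervals of the track.
#' @export
scenario_ar <- function(nbins = 12000L, C = 5L, rate = 0.1,
                        hub_rate = 0.05, ar_coef = 0.995, noise_sd = 0.1,
                        gain = 0.75, threshold = 2, excite = 3.3, L = 5L,
                        bin_size = 0.001, seed = 1L) {
  set.seed(seed)
  z <- numeric(nbins)
  sd_stat <- noise_sd / sqrt(1 - ar_coef^2)
  z[1L] <- stats::rnorm(1L, 0, sd_stat)
  innov <- stats::rnorm(nbins - 1L, 0, noise_sd)
  for (t in 2:nbins) z[t] <- ar_coef * z[t - 1L] + innov[t - 1L]
  a <- c(rep(stats::qlogis(rate), C - 1L), stats::qlogis(hub_rate))
  b <- hub_couplings(C, L, excite)
  par <- neuron_params(a, b)
  k3 <- order_marks(C, 3L)
  gamma <- matrix(gain * z, nbins, length(k3), dimnames = list(NULL, k3))
  third <- nbins %/% 3L
  gate <- as.numeric(seq_len(nbins) <= third | seq_len(nbins) > 2L * third)
  hi <- rle(z > threshold)
  ends <- cumsum(hi$lengths)
  starts <- ends - hi$lengths + 1L
  epochs <- rbind(
    data.frame(start = c(1L, third + 1L, 2L * third + 1L),
               end = c(third, 2L * third, nbins),
               label = c("endogenous_r4", "chance_r4", "endogenous_r4")),
    if (any(hi$values))
      data.frame(start = starts[hi$values], end = ends[hi$values],
                 label = "track_above_threshold"))
  # spike draws use a derived seed so they do not replay the track's stream
  simulate_ensemble(C, nbins, par, gamma = gamma, theta_gate = gate, L = L,
                    bin_size = bin_size, seed = (seed + 1000003L) %% .Machine$integer.max,
                    epochs = epochs, track = z)
}
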