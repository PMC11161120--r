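# Sequential weighted estimation: recursion identities, oracles, greedy
# selection, de-sparsified intervals.

test_that("the recursive weighted table reproduces the direct weighted sum", {
  for (seed in 1:4) {
    sc <- sim_null(C = 3, nbins = 200, rate = 0.2, seed = seed + 60)
    ms <- mark_space(sc$spikes, N_thr = 0)
    X <- history_covariates(sc$spikes, L = 2)
    o <- hocoord:::outcome_index(ms$marks, ms$reliable)
    set.seed(seed)
    beta <- runif(1, 0.5, 0.99)
    par <- mkpp_params(rnorm(length(ms$reliable), -2, 0.5),
                       matrix(rnorm(6 * length(ms$reliable), 0, 0.3), 6),
                       marks = ms$reliable)
    W <- 10L
    tab <- hocoord:::new_wtable(6L, length(ms$reliable))
    for (k in 1:20) {
      idx <- ((k - 1) * W + 1):(k * W)
      hocoord:::wtable_update(tab, X[idx, , drop = FALSE], o[idx], beta)
      v <- hocoord:::wtable_view(tab)
      ll_rec <- cpp_mnl_eval(v$X, v$Wt, par$mu, par$theta, FALSE)$loglik
      ll_dir <- weighted_loglik(par, ms$marks, X, W = W, beta = beta, k = k)
      expect_lt(abs(ll_rec - ll_dir) / abs(ll_dir), 1e-8)
    }
  }
})

test_that("degenerate forgetting factors reduce to single-window sums", {
  sc <- sim_null(C = 3, nbins = 100, rate = 0.2, seed = 3)
  ms <- mark_space(sc$spikes, N_thr = 0)
  par <- mkpp_params(rep(-2, length(ms$reliable)), marks = ms$reliable)
  # beta = 0: only the current window survives, at full weight
  l5 <- window_loglik(ms$marks[41:50], NULL, par)
  expect_equal(weighted_loglik(par, ms$marks, NULL, W = 10, beta = 0, k = 5),
               l5, tolerance = 1e-12)
  # k = 1: a single term scaled by (1 - beta)
  l1 <- window_loglik(ms$marks[1:10], NULL, par)
  expect_equal(weighted_loglik(par, ms$marks, NULL, W = 10, beta = 0.9, k = 1),
               0.1 * l1, tolerance = 1e-12)
})

test_that("the history-independent fit recovers multinomial frequencies", {
  sc <- sim_null(C = 3, nbins = 3000, rate = 0.2, seed = 31)
  # single window spanning everything at beta = 0: global MLE = frequencies
  fit <- mkpp_fit(sc$spikes, W = 3000, beta = 0, history = FALSE, N_thr = 0)
  pr <- event_probs(NULL, coef(fit))
  freq <- vapply(fit$mark_space$reliable,
                 function(m) mean(fit$mark_space$marks == m), numeric(1))
  expect_equal(unname(drop(pr$p_mark)), freq, tolerance = 1e-10)
  # near-stationary adaptive estimate approaches the frequencies too
  fit2 <- mkpp_fit(sc$spikes, W = 10, beta = 0.99, history = FALSE, N_thr = 0)
  pr2 <- event_probs(NULL, coef(fit2))
  se <- sqrt(freq * (1 - freq) / effective_window(10, 0.99))
  expect_true(all(abs(drop(pr2$p_mark) - freq) < 3 * se + 5e-3))
})

test_that("base rates of vanished marks are driven to the floor", {
  tab <- hocoord:::new_wtable(0L, 2L)
  hocoord:::wtable_update(tab, NULL, c(1L, 2L, 0L, 0L), beta = 0.5)
  hocoord:::wtable_update(tab, NULL, rep(0L, 4L), beta = 0.5)
  mu <- hocoord:::hf_closed_form(tab, mu_floor = -25)
  expect_true(all(is.finite(mu)))
  tab0 <- hocoord:::new_wtable(0L, 2L)
  hocoord:::wtable_update(tab0, NULL, rep(0L, 4L), beta = 0.5)
  expect_equal(hocoord:::hf_closed_form(tab0, mu_floor = -25), rep(-25, 2))
})

test_that("a zero sparsity budget reduces the greedy fit to the
           history-independent fit", {
  sc <- sim_null(C = 3, nbins = 500, rate = 0.2, seed = 41)
  f0 <- mkpp_fit(sc$spikes, W = 10, beta = 0.9, history = TRUE, L = 2,
                 sparsity = 0)
  ff <- mkpp_fit(sc$spikes, W = 10, beta = 0.9, history = FALSE)
  expect_equal(f0$mu, ff$mu, tolerance = 1e-5)
  expect_true(all(vapply(f0$theta_traj, function(t) nrow(t$support) == 0L,
                         logical(1))))
})

test_that("with a full budget and no penalty the greedy fit attains the
           unconstrained weighted MLE", {
  sc <- sim_null(C = 3, nbins = 300, rate = 0.25, seed = 51)
  fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.9, history = TRUE, L = 1,
                  sparsity = 3, ridge = 0, N_thr = 0)
  ms <- fit$mark_space
  M <- length(ms$reliable)
  # independent oracle: direct numerical maximization of the weighted
  # log-likelihood over all parameters at the final window
  X <- history_covariates(sc$spikes, L = 1)
  obj <- function(p) {
    par <- mkpp_params(p[1:M], matrix(p[-(1:M)], 3, M), marks = ms$reliable)
    -weighted_loglik(par, ms$marks, X, W = 10, beta = 0.9)
  }
  p0 <- c(fit$mu[, fit$K], rep(0, 3 * M))
  opt <- optim(p0, obj, method = "BFGS", control = list(maxit = 500))
  expect_lt(abs(fit$ll_beta[fit$K] - (-opt$value)), 1e-4)
})

test_that("a dominant true coupling is selected first", {
  # greedy selection from an empty support on the adapted weighted data
  # must pick the one generating coupling before anything else
  hits <- 0L
  for (seed in 1:10) {
    theta <- matrix(0, 3, 7)
    theta[1, 3] <- 2.5  # mark {1,2} driven by neuron 1's previous spike
    par <- mkpp_params(rep(-3, 7), theta, marks = 1:7)
    sc <- simulate_ensemble(3, 800, par, L = 1, seed = 700 + seed)
    ms <- mark_space(sc$spikes, N_thr = 0)
    X <- history_covariates(sc$spikes, L = 1)
    o <- hocoord:::outcome_index(ms$marks, ms$reliable)
    tab <- hocoord:::new_wtable(3L, length(ms$reliable))
    for (k in seq_len(80))
      hocoord:::wtable_update(tab, X[((k - 1) * 10 + 1):(k * 10), ,
                                     drop = FALSE],
                              o[((k - 1) * 10 + 1):(k * 10)], 0.95)
    mu0 <- hocoord:::hf_closed_form(tab)
    f <- hocoord:::fit_mnl(tab, mu0, matrix(0, 3, length(ms$reliable)),
                           matrix(integer(), 0, 2),
                           rep(TRUE, length(ms$reliable)))
    v <- hocoord:::wtable_view(tab)
    G <- abs(cpp_mnl_eval(v$X, v$Wt, f$mu, f$theta, TRUE)$gtheta)
    pick <- which(G == max(G), arr.ind = TRUE)[1L, ]
    if (ms$reliable[pick[2L]] == 3 && pick[1L] == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("de-sparsified estimates are a no-op at an interior optimum and
           cover the closed-form MLE", {
  sc <- sim_null(C = 3, nbins = 1500, rate = 0.25, seed = 61)
  fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.95, history = TRUE, L = 1,
                  sparsity = 3, ridge = 0, N_thr = 0)
  ds <- desparsify(fit)
  on_support <- ds$covariate == "(base rate)" |
    paste(ds$mark, ds$covariate) %in%
      paste(fit$mark_space$reliable[fit$theta_traj[[fit$K]]$support[, 1L]],
            colnames(fit$X)[fit$theta_traj[[fit$K]]$support[, 2L]])
  expect_lt(max(abs(ds$debiased - ds$estimate)[on_support]), 1e-4)
  expect_true(all(ds$se > 0))
  # deterministic edge case: single mark at a constant rate; the interval
  # covers the closed-form MLE of its base rate
  counts <- matrix(0L, 2, 400)
  counts[1, seq(4, 400, by = 4)] <- 1L
  sp <- suppressWarnings(spike_ensemble(counts, 0.001))
  hf <- mkpp_fit(sp, W = 10, beta = 0.95, history = FALSE, N_thr = 0)
  ci <- confint(hf)
  mle <- log(0.25 / 0.75)
  expect_lt(ci[1, "lower"], mle)
  expect_gt(ci[1, "upper"], mle)
})

test_that("fit methods expose the model: print, coef, logLik, predict,
           residuals, simulate", {
  sc <- sim_null(C = 3, nbins = 400, rate = 0.2, seed = 71)
  fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.9, history = TRUE, L = 2)
  expect_output(print(fit), "Adaptive MkPP model")
  expect_output(print(summary(fit)), "base rates")
  par <- coef(fit, window = 5)
  expect_s3_class(par, "mkpp_params")
  expect_equal(unname(AIC(logLik(fit)) > 0), TRUE)
  P <- predict(fit)
  expect_equal(dim(P), c(400L, length(fit$mark_space$reliable) + 1L))
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  U <- predict(fit, type = "log_odds")
  expect_equal(ncol(U), length(fit$mark_space$reliable))
  R <- residuals(fit)
  expect_equal(dim(R), c(400L, length(fit$mark_space$reliable)))
  expect_true(all(abs(colMeans(R)) < 0.05))
  sims <- simulate(fit, nsim = 2, seed = 1, nbins = 100)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "spike_ensemble")
})
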