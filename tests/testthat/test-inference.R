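# Nested-hypothesis machinery: null composition, exogenous factors,
# thresholding, non-centrality smoothing, J-statistic, end-to-end runs.

test_that("null log-odds compose independence from per-neuron marginals", {
  # C = 2: the joint-pattern log-odds under independence are logit(pi1) +
  # logit(pi2), computable directly from the exact-pattern probabilities
  par <- neuron_params(c(-2, -1))
  u0 <- null_log_odds(NULL, par, m = 3, C = 2)
  pr <- event_probs(NULL, par)
  pi1 <- pr$p_mark[1, "1"] + pr$p_mark[1, "3"]
  pi2 <- pr$p_mark[1, "2"] + pr$p_mark[1, "3"]
  oracle <- unname(log(pi1 * pi2 / ((1 - pi1) * (1 - pi2))))
  expect_equal(unname(u0[1, 1]), oracle, tolerance = 1e-12)
  # under the independence composition the model's own log-odds agree
  expect_equal(unname(u0[1, 1]), log_odds(NULL, par, 3), tolerance = 1e-12)
})

test_that("null log-odds are symmetric for exchangeable neurons and
           unconstrained at order 1", {
  par <- neuron_params(rep(-2.5, 5))
  k3 <- order_marks(5, 3)
  u0 <- null_log_odds(NULL, par, m = k3, C = 5)
  expect_lt(diff(range(u0[1, ])), 1e-12)
  u1 <- null_log_odds(NULL, par, m = 1, C = 5)
  expect_equal(unname(u1[1, 1]), log_odds(NULL, par, 1))
})

test_that("exogenous factor averages the log-odds gap", {
  u0 <- matrix(rnorm(50), 10, 5)
  expect_equal(unname(exogenous_factor(u0, u0)), rep(0, 5))
  expect_equal(unname(exogenous_factor(u0 + 0.7, u0)), rep(0.7, 5),
               tolerance = 1e-12)
})

test_that("per-window thresholding uses the chi-square quantile and the
           net exogenous sign", {
  expect_equal(test_window(0, 10, 0.01, 1), 0)
  expect_equal(test_window(24, 10, 0.01, 2.5), 1)   # q_{0.99}(chi2_10)=23.2
  expect_equal(test_window(24, 10, 0.01, -2.5), -1)
  expect_equal(test_window(23, 10, 0.01, 2.5), 0)
  expect_equal(test_window(24, 10, 0.05, -1), -1)
})

test_that("non-centrality smoothing recovers constant and piecewise levels", {
  M <- 10
  sm0 <- smooth_noncentrality(rep(M, 100), M)
  expect_true(all(sm0$nu < 0.5))
  sm1 <- smooth_noncentrality(rep(M + 100, 100), M)
  expect_true(all(abs(sm1$nu[10:100] - 100) < 5))
  set.seed(77)
  nu_true <- c(rep(0, 150), rep(300, 150))
  D <- rchisq(300, df = M, ncp = nu_true)
  sm <- smooth_noncentrality(D, M)
  expect_lt(mean(sm$nu[100:140]), 60)
  plateau <- mean(sm$nu[250:300])
  expect_lt(abs(plateau - 300) / 300, 0.2)
  expect_true(all(sm$nu >= 0))
})

test_that("the J-statistic respects its conventions", {
  M <- 10; alpha <- 0.01
  expect_equal(j_statistic(0, M, alpha, 1), 0)
  expect_equal(j_statistic(1e7, M, alpha, 1), 1 - alpha, tolerance = 1e-6)
  expect_equal(j_statistic(1e7, M, alpha, -1), -(1 - alpha), tolerance = 1e-6)
  nus <- c(0, 2, 50, 327)
  J <- j_statistic(nus, M, alpha, 1)
  expect_true(all(J >= 0 & J <= 1 - alpha))
  expect_true(all(diff(J) >= 0))  # power grows with the non-centrality
  # J = 0 exactly when the null is not rejected
  expect_equal(j_statistic(nus, M, alpha, 0), rep(0, 4))
  # strong coordination: nu = 327 at M = 10 gives |J| essentially 1 - alpha
  expect_gt(j_statistic(327, 10, 0.01, 1), 0.98)
})

test_that("orders with no reliable marks are skipped with a report", {
  sc <- sim_null(C = 3, nbins = 600, rate = 0.1, seed = 9)
  fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.95, history = FALSE, N_thr = 1)
  expect_message(ct <- coordination_test(fit, r = c(2, 3), alpha = 0.01),
                 "skipped")
  expect_true(3 %in% ct$skipped || !(3 %in% ct$results$r) ||
                all(is.na(ct$results$D[ct$results$r == 3])))
  expect_error(coordination_test(fit, r = 1), ">= 2")
})

test_that("raw deviances are nested and facilitation is detected end-to-end", {
  sc <- scenario_step(n_realizations = 1, nbins = 4000, seed = 17)[[1]]
  fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.99, history = FALSE)
  ct <- coordination_test(fit, r = 3, alpha = 0.01)
  res <- ct$results
  # nestedness of the raw (unscaled, un-de-biased) deviance
  expect_true(all(res$raw_dev >= -1e-6))
  # facilitated second half (past the adaptation transient): positive net
  # exogenous factor and rejections
  late <- res$window > 320
  expect_gt(mean(res$sum_gamma[late]), 0)
  expect_gt(mean(res$h[late] == 1), 0.5)
  # results table is tidy: one row per (window, r)
  expect_equal(nrow(res), fit$K)
  expect_true(all(c("window", "time_start", "r", "D", "nu_hat", "h", "J",
                    "sum_gamma") %in% colnames(res)))
  expect_s3_class(summary(ct), "data.frame")
})

test_that("history-free exogenous factors match the history-dependent
           decomposition within estimation error", {
  # gamma_free ~ gamma_hist + xbar' theta on data with real history structure
  sc <- scenario_square_wave(nbins = 4000, half_period = 1000, seed = 3)
  fitH <- mkpp_fit(sc$spikes, W = 10, beta = 0.95, history = TRUE, L = 5,
                   ridge = 1e-3)
  ctH <- coordination_test(fitH, r = 3)
  fitF <- mkpp_fit(sc$spikes, W = 10, beta = 0.95, history = FALSE)
  ctF <- coordination_test(fitF, r = 3)
  gF <- colSums(ctF$gamma[["3"]])
  gH <- colSums(ctH$gamma[["3"]]) + colSums(ctH$endo[["3"]])
  keep <- ctH$results$window > 50
  expect_gt(cor(gF[keep], gH[keep]), 0.6)
})
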