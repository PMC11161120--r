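# Multinomial GLM likelihood: probabilities, log-likelihood, gradients.

rand_params <- function(C = 3, L = 1, seed = 1, density = 0.5) {
  set.seed(seed)
  marks <- seq_len(2^C - 1)
  mu <- rnorm(length(marks), -3, 1)
  theta <- matrix(rnorm(C * L * length(marks)) *
                    rbinom(C * L * length(marks), 1, density),
                  C * L, length(marks))
  mkpp_params(mu, theta, marks = marks)
}

test_that("event probabilities normalize exactly and stay in (0,1)", {
  for (seed in 1:5) {
    par <- rand_params(C = 3, L = 2, seed = seed)
    set.seed(seed + 100)
    X <- matrix(rbinom(20 * 6, 1, 0.3), 20, 6)
    pr <- event_probs(X, par)
    expect_true(all(abs(pr$p_none + rowSums(pr$p_mark) - 1) < 1e-12))
    expect_true(all(pr$p_mark > 0 & pr$p_mark < 1))
    expect_true(all(pr$p_none > 0 & pr$p_none < 1))
    # ground-process identity: lambda*(g) = sum over marks
    expect_equal(1 - pr$p_none, rowSums(pr$p_mark), tolerance = 1e-12)
  }
})

test_that("log-odds reduce to the base rate without history", {
  par <- mkpp_params(c(`1` = -3, `2` = -2.5, `3` = -4))
  expect_equal(log_odds(NULL, par, 1), -3)
  X <- matrix(rbinom(30, 1, 0.5), 10, 3)
  expect_equal(log_odds(X, par, 3), rep(-4, 10))
  expect_error(log_odds(NULL, par, 7), "not in the model")
  # single-covariate dot product
  par2 <- mkpp_params(c(`1` = 0), theta = matrix(c(1, 0, 0), 3, 1))
  expect_equal(log_odds(matrix(c(1, 0, 0), 1, 3), par2, 1), 1)
})

test_that("closed-form softmax values match hand computation", {
  # two marks with mu = -2, no history: p = e^-2 / (1 + 2 e^-2) each
  par <- mkpp_params(c(`1` = -2, `2` = -2))
  pr <- event_probs(NULL, par)
  expect_equal(drop(pr$p_mark), rep(exp(-2) / (1 + 2 * exp(-2)), 2),
               ignore_attr = TRUE)
  # single mark at mu = 0: logistic at zero
  pr1 <- event_probs(NULL, mkpp_params(c(`1` = 0)))
  expect_equal(drop(pr1$p_mark), 0.5, ignore_attr = TRUE)
  # symmetry across 31 equal marks
  par31 <- mkpp_params(stats::setNames(rep(-4, 31), 1:31))
  pr31 <- event_probs(NULL, par31)
  expect_equal(max(pr31$p_mark) - min(pr31$p_mark), 0)
})

test_that("window log-likelihood matches a per-bin categorical oracle", {
  set.seed(3)
  par <- rand_params(C = 3, L = 2, seed = 3)
  X <- matrix(rbinom(25 * 6, 1, 0.3), 25, 6)
  o <- sample(c(0, par$marks), 25, replace = TRUE)
  ll <- window_loglik(o, X, par)
  # oracle: per-bin categorical log-pmf summed independently
  oracle <- 0
  for (t in 1:25) {
    pr <- event_probs(X[t, , drop = FALSE], par)
    p <- c(pr$p_none, pr$p_mark)
    names(p) <- c("0", par$marks)
    oracle <- oracle + log(p[[as.character(o[t])]])
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
  expect_lte(ll, 0)
  # single bin, single mark at p = 1/2
  par1 <- mkpp_params(c(`1` = 0))
  expect_equal(window_loglik(1, NULL, par1), log(0.5))
  # all-quiet window at very negative mu is near zero from below
  parq <- mkpp_params(c(`1` = -15))
  llq <- window_loglik(rep(0, 50), NULL, parq)
  expect_lt(llq, 0)
  expect_gt(llq, -1e-4)
})

test_that("analytic gradient matches finite differences", {
  par <- rand_params(C = 3, L = 1, seed = 9)
  set.seed(9)
  X <- matrix(rbinom(30 * 3, 1, 0.4), 30, 3)
  o <- sample(c(0, par$marks), 30, replace = TRUE)
  g <- grad_window_loglik(o, X, par)
  h <- 1e-6
  for (j in c(1, 4, 7)) {
    up <- par; up$mu[j] <- up$mu[j] + h
    dn <- par; dn$mu[j] <- dn$mu[j] - h
    num <- (window_loglik(o, X, up) - window_loglik(o, X, dn)) / (2 * h)
    expect_lt(abs(g$gmu[j] - num) / (abs(num) + 1e-3), 1e-5)
  }
  for (idx in list(c(1, 2), c(3, 5))) {
    up <- par; up$theta[idx[1], idx[2]] <- up$theta[idx[1], idx[2]] + h
    dn <- par; dn$theta[idx[1], idx[2]] <- dn$theta[idx[1], idx[2]] - h
    num <- (window_loglik(o, X, up) - window_loglik(o, X, dn)) / (2 * h)
    expect_lt(abs(g$gtheta[idx[1], idx[2]] - num) / (abs(num) + 1e-3), 1e-5)
  }
  # all-no-event window: d l / d mu is strictly negative
  g0 <- grad_window_loglik(rep(0, 30), X, par)
  expect_true(all(g0$gmu < 0))
})

test_that("a small step along the gradient does not decrease the likelihood", {
  for (seed in 1:3) {
    par <- rand_params(C = 3, L = 1, seed = seed + 20)
    set.seed(seed + 20)
    X <- matrix(rbinom(40 * 3, 1, 0.4), 40, 3)
    o <- sample(c(0, par$marks), 40, replace = TRUE)
    g <- grad_window_loglik(o, X, par)
    eps <- 1e-4 / max(abs(c(g$gmu, g$gtheta)), 1)
    up <- par
    up$mu <- par$mu + eps * g$gmu
    up$theta <- par$theta + eps * g$gtheta
    expect_gte(window_loglik(o, X, up), window_loglik(o, X, par))
  }
})

test_that("history covariates use only strictly earlier bins, lag-major", {
  counts <- matrix(0L, 2, 8)
  counts[1, 3] <- 1L
  counts[2, 6] <- 1L
  sp <- spike_ensemble(counts, 0.01)
  X <- history_covariates(sp, L = 3)
  expect_equal(dim(X), c(8, 6))
  expect_equal(colnames(X)[1:2], c("c1.l1", "c2.l1"))
  # neuron 1's spike at bin 3 appears at lag 1 in bin 4, lag 2 in bin 5...
  expect_equal(unname(X[4, "c1.l1"]), 1)
  expect_equal(unname(X[5, "c1.l2"]), 1)
  expect_equal(unname(X[6, "c1.l3"]), 1)
  expect_equal(unname(X[3, "c1.l1"]), 0)  # never the same bin
  expect_equal(sum(X[, "c2.l1"]), 1)
  expect_equal(unname(which(X[, "c2.l1"] == 1)), 7)
})

test_that("the log-spaced history basis pools lags into windows", {
  counts <- matrix(0L, 2, 12)
  counts[1, c(2, 5)] <- 1L
  sp <- spike_ensemble(counts, 0.01)
  X <- history_covariates(sp, L = 8, basis = "log")
  # groups: 1, 2, 3-4, 5-8 -> 4 groups x 2 neurons
  expect_equal(ncol(X), 8)
  expect_true("c1.l3_4" %in% colnames(X))
  # the spike at bin 2 is visible at lag 1 (bin 3), lags 3-4 (bins 5-6),
  # and lags 5-8 (bins 7-10)
  expect_equal(unname(X[3, "c1.l1"]), 1)
  expect_equal(unname(X[5, "c1.l3_4"]), 1)
  expect_equal(unname(X[6, "c1.l3_4"]), 1)
  expect_equal(unname(X[10, "c1.l5_8"]), 1)
  expect_equal(unname(X[4, "c1.l5_8"]), 0)
  # a fit runs with the pooled basis
  sc <- sim_null(C = 3, nbins = 300, rate = 0.2, seed = 91)
  fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.9, history = TRUE, L = 8,
                  basis = "log")
  expect_equal(fit$p, 3 * 4)
})
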