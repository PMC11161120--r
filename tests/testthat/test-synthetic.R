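# Ground-truth simulator: determinism, sampling correctness, scenarios.

test_that("fixed seeds give bit-identical realizations", {
  a <- sim_null(C = 4, nbins = 300, seed = 11)
  b <- sim_null(C = 4, nbins = 300, seed = 11)
  expect_identical(a$spikes$counts, b$spikes$counts)
  c <- sim_null(C = 4, nbins = 300, seed = 12)
  expect_false(identical(a$spikes$counts, c$spikes$counts))
})

test_that("per-neuron composition makes neurons exactly independent", {
  # with mu(m) = sum a_c over the full mark space, the categorical model
  # factorizes: the normalizer is prod_c (1 + exp(a_c))
  a <- c(-2.5, -3, -1.5)
  par <- neuron_params(a)
  pr <- event_probs(NULL, par)
  expect_equal(drop(pr$p_none), prod(1 / (1 + exp(a))), tolerance = 1e-12)
  # marginal per-neuron probability equals the logistic of its own logit
  patt <- vapply(par$marks, decode_mark, integer(3), C = 3)
  Pi <- drop(pr$p_mark %*% t(patt))
  expect_equal(unname(Pi), plogis(a), tolerance = 1e-12)
})

test_that("empirical mark frequencies match the softmax probabilities", {
  par <- mkpp_params(stats::setNames(rep(-2.5, 7), 1:7))
  sc <- simulate_ensemble(3, 20000, par, L = 1, seed = 99)
  pr <- event_probs(NULL, par)
  for (m in 1:7) {
    f <- mean(sc$marks_seq == m)
    p <- pr$p_mark[1, as.character(m)]
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(f - p), 3 * se + 1e-9)
  }
})

test_that("an overwhelming exogenous drive saturates its mark", {
  gamma <- matrix(25, 200, 1, dimnames = list(NULL, "3"))
  par <- neuron_params(rep(-3, 3))
  sc <- simulate_ensemble(3, 200, par, gamma = gamma, L = 1, seed = 5)
  expect_true(all(sc$marks_seq == 3))
})

test_that("step scenario is null first, facilitated second", {
  scs <- scenario_step(n_realizations = 6, nbins = 1200, seed = 21)
  expect_length(scs, 6)
  more <- vapply(scs, function(sc) {
    expect_true(all(sc$gamma_true[1:600, ] == 0))
    expect_true(all(sc$gamma_true[601:1200, ] == 1.5))
    k3 <- mark_order(pmax(sc$marks_seq, 1)) == 3 & sc$marks_seq > 0
    sum(k3[601:1200]) > sum(k3[1:600])
  }, logical(1))
  expect_true(all(more))
  expect_equal(scs[[1]]$epochs$label, c("null", "facilitation"))
})

test_that("square-wave scenario alternates epochs and couples 4th order", {
  sc <- scenario_square_wave(nbins = 4000, half_period = 1000, seed = 31)
  expect_equal(nrow(sc$epochs), 4)
  expect_equal(sc$epochs$label,
               rep(c("facilitation", "suppression"), 2))
  expect_equal(sc$epochs$end - sc$epochs$start + 1, rep(1000, 4))
  ord <- ifelse(sc$marks_seq > 0, mark_order(pmax(sc$marks_seq, 1)), 0)
  fac <- c(1:1000, 2001:3000)
  expect_gt(sum(ord[fac] == 3), sum(ord[-fac] == 3))
  # ablation: zeroing the hub coupling removes the 4th-order excess
  sc0 <- scenario_square_wave(nbins = 4000, half_period = 1000, seed = 31,
                              excite = 0)
  ord0 <- ifelse(sc0$marks_seq > 0, mark_order(pmax(sc0$marks_seq, 1)), 0)
  expect_gt(sum(ord == 4), 2 * sum(ord0 == 4))
})

test_that("AR scenario stores its track and gates 4th-order endogeneity", {
  sc <- scenario_ar(nbins = 3000, seed = 41)
  expect_length(sc$track, 3000)
  expect_equal(unname(cor(sc$gamma_true[, 1], sc$track)), 1)
  ord <- ifelse(sc$marks_seq > 0, mark_order(pmax(sc$marks_seq, 1)), 0)
  third <- 1000
  outer_r4 <- sum(ord[c(1:third, (2 * third + 1):3000)] == 4)
  middle_r4 <- sum(ord[(third + 1):(2 * third)] == 4)
  expect_gt(outer_r4, middle_r4)
  sc2 <- scenario_ar(nbins = 3000, seed = 41)
  expect_identical(sc$spikes$counts, sc2$spikes$counts)
})

test_that("the likelihood prefers the generating parameters", {
  sc <- sim_null(C = 3, nbins = 8000, rate = 0.15, seed = 55)
  par <- sc$params
  set.seed(56)
  wins <- split(1:8000, rep(1:40, each = 200))
  better <- vapply(wins, function(idx) {
    pert <- par
    pert$mu <- par$mu + 0.5 * sample(c(-1, 1), length(par$mu), replace = TRUE)
    window_loglik(sc$marks_seq[idx], NULL, par) >
      window_loglik(sc$marks_seq[idx], NULL, pert)
  }, logical(1))
  expect_gte(mean(better), 0.95)
})
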