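# Dynamic inference of rth-order spiking coordination.
#
# The null hypothesis of the rth-order test is that rth-order simultaneous
# spikes occur as often as they would between independent units given
# ensemble spiking history. Per window the full adaptive fit is compared to
# a reduced fit whose base rates for the tested marks are pinned at
# mu_0 = mu_hat - gamma_hat, where gamma_hat is the average gap between the
# model's log-odds and the log-odds composed under conditional independence
# from the model's per-neuron marginals. The scaled, de-biased deviance
# difference has a chi-square(M) limit under the null and a non-central
# chi-square(M, nu) limit under the alternative; nu is tracked over windows
# by a state-space smoother and summarized by a signed Youden J-statistic.

# independence-composed log-odds: u0(m) = sum_{c in pattern(m)} logit(pi_c)
# P_mark: n x M matrix of per-bin mark probabilities; patt: C x M patterns
indep_log_odds <- function(P_mark, patt, test_pos) {
  Pi <- P_mark %*% t(patt)  # n x C per-neuron marginal event probabilities
  Pi <- pmin(pmax(Pi, 1e-12), 1 - 1e-12)
  Lg <- stats::qlogis(Pi)
  out <- vapply(test_pos, function(j)
    rowSums(Lg[, patt[, j] == 1L, drop = FALSE]), numeric(nrow(P_mark)))
  matrix(out, nrow = nrow(P_mark))
}

#' Log-odds of marks under the conditional-independence null
#'
#' Composes, per bin, the log-odds of each requested mark occurring if its
#' constituent neurons spiked independently given ensemble history: the
#' model's mark probabilities are marginalized to per-neuron event
#' probabilities `pi_c`, the exact-pattern probability under independence is
#' the product over spiking neurons times the product of complements over
#' silent ones, and the log-odds against the composed no-event probability
#' reduce to `sum_{c in pattern} logit(pi_c)`. Order-1 marks are returned
#' unconstrained (their null is the model itself). Probabilities are clamped
#' to `[1e-12, 1 - 1e-12]` before the logit; a warning reports clamping.
#'
#' @param X covariate rows (bins) or NULL for the history-independent model.
#' @param params an [mkpp_params] over the reliable marks.
#' @param m mark indices to compose (must be in `params$marks`).
#' @param C number of neurons.
#' @return Matrix, rows = bins, columns = marks in `m`.
#' @export
null_log_odds <- function(X, params, m, C) {
  pos <- match(m, params$marks)
  if (anyNA(pos)) stop("requested marks are not in the model")
  patt <- vapply(params$marks, decode_mark, integer(C), C = C)
  pr <- event_probs(X, params)
  P <- pr$p_mark
  Pi_raw <- P %*% t(patt)
  if (any(Pi_raw < 1e-12) || any(Pi_raw > 1 - 1e-12))
    warning("per-neuron marginals clamped to [1e-12, 1-1e-12]")
  u0 <- indep_log_odds(P, patt, pos)
  ord <- mark_order(params$marks[pos])
  if (any(ord == 1L)) {
    for (j in which(ord == 1L)) {
      u <- log_odds(X, params, params$marks[pos[j]])
      u0[, j] <- if (length(u) == 1L) rep(u, nrow(u0)) else u
    }
  }
  colnames(u0) <- m
  u0
}

#' Estimated exogenous factor of a mark over a window
#'
#' `gamma_hat(m)` is the average, over the window's bins, of the difference
#' between the model's log-odds `u_t(m)` and the conditional-independence
#' log-odds `u_{0,t}(m)`. Positive values indicate facilitation beyond what
#' independence given ensemble history explains; negative values indicate
#' suppression.
#'
#' @param u matrix of full-model log-odds (bins x marks).
#' @param u0 matrix of null log-odds of the same shape.
#' @return Named vector of per-mark averages.
#' @export
exogenous_factor <- function(u, u0) {
  stopifnot(all(dim(u) == dim(u0)))
  colMeans(u - u0)
}

# Plug-in bias of the deviance from estimated base-rate pins.
#
# Under the null the deviance is approximately scale * gamma_hat' Ibar
# gamma_hat, with Ibar the information of the tested base rates after
# profiling out the free parameters (Schur complement). gamma_hat inherits
# noise both from the tested base rates themselves and from the composed
# independence log-odds u0 (through every parameter of the model), so
#   E[D] = tr( Ibar (S - J) A^-1 (S - J)' ),
# where A is the observed information over the fitted coordinate set,
# S maps parameters to the window-average model log-odds of the tested
# marks (indicator for mu, average covariate for theta), and J is the
# Jacobian of the window-average u0. When u0 is noise-free (J = 0) the
# identity (A^-1)_tt = Ibar^-1 gives E[D] = M, the chi-square mean; the
# de-biasing therefore subtracts (trace - M) from the scaled deviance.
pin_bias_term <- function(v, full, pos, Xw, patt, ridge) {
  M_all <- length(full$mu)
  sup <- full$support
  ns <- nrow(sup)
  coord_mark <- as.integer(c(seq_len(M_all), if (ns) sup[, 1L]))
  coord_cov <- as.integer(c(rep(0L, M_all), if (ns) sup[, 2L]))
  d <- length(coord_mark)
  H <- cpp_mnl_hess(v$X, v$Wt, full$mu, full$theta, coord_mark, coord_cov)
  A <- -H
  if (ridge > 0) diag(A) <- diag(A) + c(rep(0, M_all), rep(ridge, ns))
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv))
    Ainv <- solve(A + diag(1e-6 * max(diag(A), 1), d))
  Mi <- length(pos)
  W_ <- if (is.null(Xw)) 1L else nrow(Xw)
  # per-bin probabilities under the full model at the window's covariates
  if (is.null(Xw)) {
    pr <- event_probs(NULL, mkpp_params(full$mu, marks = seq_len(M_all)))
    P <- matrix(drop(pr$p_mark), W_, M_all, byrow = TRUE)
  } else {
    P <- cpp_mnl_probs(Xw, full$mu, full$theta)[, -1L, drop = FALSE]
  }
  C <- nrow(patt)
  Pi <- pmin(pmax(P %*% t(patt), 1e-12), 1 - 1e-12)  # W x C marginals
  xbar <- if (is.null(Xw)) NULL else colMeans(Xw)
  # S: parameter loading of the window-average model log-odds
  S <- matrix(0, Mi, d)
  for (i in seq_len(Mi)) {
    S[i, pos[i]] <- 1
    if (ns) {
      own <- which(sup[, 1L] == pos[i])
      if (length(own)) S[i, M_all + own] <- xbar[sup[own, 2L]]
    }
  }
  # J: Jacobian of the window-average composed null log-odds
  # du0(m)/dw_j = mean_t sum_{c in m} [x_aj p_mj ([m_j in c] - pi_c)]
  #              / (pi_c (1 - pi_c))
  J <- matrix(0, Mi, d)
  iPi <- 1 / (Pi * (1 - Pi))
  for (j in seq_len(d)) {
    mj <- coord_mark[j]
    q <- if (coord_cov[j] == 0L) P[, mj] else Xw[, coord_cov[j]] * P[, mj]
    memb <- patt[, mj] == 1L  # neurons in the perturbing mark
    for (i in seq_len(Mi)) {
      cs <- which(patt[, pos[i]] == 1L)
      acc <- 0
      for (cc in cs)
        acc <- acc + mean(q * ((memb[cc]) - Pi[, cc]) * iPi[, cc])
      J[i, j] <- acc
    }
  }
  G <- S - J
  Vg <- G %*% Ainv %*% t(G)
  Att <- Ainv[pos, pos, drop = FALSE]
  Ibar <- tryCatch(solve(Att), error = function(e)
    solve(Att + diag(1e-8, Mi)))
  sum(diag(Ibar %*% Vg))
}

#' Adaptive estimation bias of the weighted log-likelihood
#'
#' Plug-in estimate of the upward bias of `2 * l_k^beta` at the adaptive
#' estimate. The default charges `(1 - beta) / (1 + beta)` per fitted
#' coordinate (support cardinality `d`), so that the full-minus-reduced bias
#' contributes exactly the test's degrees of freedom after scaling.
#'
#' @param d support cardinality (number of fitted coordinates).
#' @param beta forgetting factor.
#' @return Bias estimate on the scale of `l_k^beta`.
#' @export
bias_estimate <- function(d, beta) (1 - beta) / (1 + beta) * d

#' Adaptive de-biased deviance difference
#'
#' `D = (1 + beta) / (1 - beta) * (2 * (llF - llR) - (BF - BR))`. Under the
#' null of chance rth-order coordination D is asymptotically chi-square with
#' M degrees of freedom (M = number of tested marks); under the alternative
#' it is non-central chi-square.
#'
#' @param ll_full,ll_reduced weighted log-likelihoods of the two fits.
#' @param beta forgetting factor.
#' @param B_full,B_reduced bias terms (see [bias_estimate()]).
#' @return Scalar test statistic.
#' @export
deviance_difference <- function(ll_full, ll_reduced, beta,
                                B_full = 0, B_reduced = 0) {
  (1 + beta) / (1 - beta) *
    (2 * (ll_full - ll_reduced) - (B_full - B_reduced))
}

#' Per-window rejection decision
#'
#' Rejects when D exceeds the `1 - alpha` quantile of chi-square(M); the
#' rejection is signed by the summed exogenous factors of the tested marks.
#'
#' @param D deviance difference.
#' @param M degrees of freedom.
#' @param alpha test level.
#' @param net_gamma sum of the tested marks' exogenous factors.
#' @return -1, 0 or +1.
#' @export
test_window <- function(D, M, alpha, net_gamma) {
  stopifnot(M >= 1, alpha > 0, alpha < 1)
  if (is.na(D) || D <= stats::qchisq(1 - alpha, df = M)) return(0)
  s <- sign(net_gamma)
  if (s == 0) s <- 1
  s
}

#' State-space smoothing of the non-centrality parameter
#'
#' Tracks the non-centrality `nu_k` of the deviance series under a
#' random-walk state model with moment-matched Gaussian observations
#' (`D_k` has mean `M + nu_k` and variance `2M + 4 nu_k`): forward Kalman
#' filter, backward (RTS) smoother, state-noise variance estimated by EM,
#' and the smoothed state clamped at zero.
#'
#' @param D numeric vector of deviance differences.
#' @param M degrees of freedom.
#' @param q_init initial state-noise variance (default `(0.1 * M)^2`).
#' @param em_iter maximum EM iterations.
#' @return List: `nu` (smoothed non-centralities, `>= 0`), `q` (estimated
#'   state-noise variance).
#' @export
smooth_noncentrality <- function(D, M, q_init = (0.1 * M)^2, em_iter = 25L) {
  K <- length(D)
  if (K == 1L) return(list(nu = max(D - M, 0), q = q_init))
  q <- q_init
  m0 <- max(D[1L] - M, 0)
  for (em in seq_len(em_iter)) {
    mf <- Pf <- mp <- Pp <- numeric(K)
    for (k in seq_len(K)) {
      mp[k] <- if (k == 1L) m0 else mf[k - 1L]
      Pp[k] <- (if (k == 1L) 2 * M + 4 * m0 else Pf[k - 1L]) + q
      R <- 2 * M + 4 * max(mp[k], 0)
      G <- Pp[k] / (Pp[k] + R)
      mf[k] <- mp[k] + G * (D[k] - M - mp[k])
      Pf[k] <- (1 - G) * Pp[k]
    }
    ms <- mf; Ps <- Pf
    Jg <- numeric(K)
    for (k in (K - 1L):1L) {
      Jg[k] <- Pf[k] / Pp[k + 1L]
      ms[k] <- mf[k] + Jg[k] * (ms[k + 1L] - mp[k + 1L])
      Ps[k] <- Pf[k] + Jg[k]^2 * (Ps[k + 1L] - Pp[k + 1L])
    }
    # lag-one smoothed covariance and EM update of q
    Pcc <- Jg[-K] * Ps[-1L]
    dq <- (ms[-1L] - ms[-K])^2 + Ps[-1L] + Ps[-K] - 2 * Pcc
    q_new <- max(mean(dq), 1e-8)
    done <- abs(q_new - q) < 1e-3 * q
    q <- q_new
    if (done) break
  }
  list(nu = pmax(ms, 0), q = q)
}

#' Signed Youden J-statistic
#'
#' `J = h * (1 - alpha - F_{chisq(M, nu)}(q_{1 - alpha}))` with
#' `q_{1 - alpha}` the central chi-square threshold: the test's power minus
#' its level, signed by the rejection direction, and 0 when the null was not
#' rejected. Values near `+(1 - alpha)` indicate strongly facilitated
#' coordination; near `-(1 - alpha)`, strong suppression.
#'
#' @param nu non-centrality estimate (`>= 0`).
#' @param M degrees of freedom.
#' @param alpha test level.
#' @param h rejection sign from [test_window()] (vector or scalar).
#' @return Signed J in `(-(1 - alpha), 1 - alpha)`.
#' @export
j_statistic <- function(nu, M, alpha, h) {
  stopifnot(all(nu >= 0))
  q <- stats::qchisq(1 - alpha, df = M)
  h * pmax(0, 1 - alpha - stats::pchisq(q, df = M, ncp = nu))
}

# build a full theta matrix and support for window k of a fit
window_params <- function(object, k) {
  M <- nrow(object$mu)
  theta <- matrix(0, object$p, M)
  sup <- matrix(integer(), 0L, 2L)
  if (object$history && !is.null(object$theta_traj[[k]])) {
    tt <- object$theta_traj[[k]]
    sup <- tt$support
    if (nrow(sup)) theta[cbind(sup[, 2L], sup[, 1L])] <- tt$values
  }
  list(mu = object$mu[, k], theta = theta, support = sup)
}

#' Test for dynamic rth-order spiking coordination
#'
#' Runs the full per-window inference procedure on a fitted adaptive model:
#' for each window the exogenous factors of the tested marks are estimated
#' (one-pass, from the previous window's reduced model), the reduced model
#' with pinned base rates is re-fit over the full model's support, the
#' adaptive de-biased deviance difference is computed and thresholded
#' against its chi-square limit, and finally the non-centrality series is
#' smoothed and summarized by the signed Youden J-statistic.
#'
#' @param object an [mkpp_fit].
#' @param r event order(s) to test, each at least 2.
#' @param alpha per-window test level.
#' @param bias bias estimator for the deviance de-biasing: `"none"`
#'   (default: the full and reduced fits' overfitting biases cancel because
#'   the reduced model's base-rate pins are themselves estimated),
#'   `"plugin"` (trace-form plug-in for the estimation noise of the pins),
#'   or `"support"` (proportional to support cardinality, so the
#'   full-minus-reduced bias equals the test's degrees of freedom). The
#'   default was selected by a null-calibration study: it is the convention
#'   under which the null deviances match their chi-square limit.
#' @param gamma_source model whose conditional-independence composition
#'   supplies the null log-odds `u_0`: `"full"` (default; the current
#'   window's full fit, matching the procedure's evaluation order) or
#'   `"reduced_prev"` (the previous window's reduced fit).
#' @param inner_iter number of gamma/pin fixed-point passes per window
#'   (only meaningful with `gamma_source = "reduced_prev"`).
#' @param p_adjust optional Benjamini-Hochberg correction across the tested
#'   orders within each window (off by default).
#' @return Object of class `coord_test`: `results` data frame with columns
#'   `window`, `time_start`, `r`, `D`, `raw_dev`, `nu_hat`, `h`, `J`,
#'   `sum_gamma`; per-order exogenous-factor trajectories `gamma`; for
#'   history-dependent fits also `endo`, the per-window average endogenous
#'   contribution `xbar' theta` of each tested mark; `skipped` lists orders
#'   with no reliable marks.
#' @examples
#' sc <- scenario_step(n_realizations = 1, nbins = 1000, seed = 7)[[1]]
#' fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.95, history = FALSE)
#' ct <- coordination_test(fit, r = 3)
#' ct
#' @export
coordination_test <- function(object, r = 3L, alpha = 0.01,
                              bias = c("none", "plugin", "support"),
                              gamma_source = c("full", "reduced_prev"),
                              inner_iter = 1L,
                              p_adjust = c("none", "BH")) {
  stopifnot(inherits(object, "mkpp_fit"))
  bias <- match.arg(bias)
  gamma_source <- match.arg(gamma_source)
  p_adjust <- match.arg(p_adjust)
  r <- sort(unique(as.integer(r)))
  if (any(r < 2L)) stop("'r' must be >= 2 (order-1 events have no independence null)")
  ms <- object$mark_space
  C <- ms$n_neurons
  reliable <- ms$reliable
  M_all <- length(reliable)
  patt <- vapply(reliable, decode_mark, integer(C), C = C)
  W <- object$W; beta <- object$beta; K <- object$K
  scale <- (1 + beta) / (1 - beta)
  test_pos <- lapply(r, function(ri) which(ms$order_of == ri))
  names(test_pos) <- r
  skipped <- r[lengths(test_pos) == 0L]
  r_run <- r[lengths(test_pos) > 0L]
  if (length(skipped))
    message("no reliable marks of order ", paste(skipped, collapse = ", "),
            ": order(s) skipped")
  tab <- new_wtable(object$p, M_all)
  res <- list()
  gamma_traj <- endo_traj <- stats::setNames(vector("list", length(r_run)),
                                             r_run)
  for (ri in as.character(r_run)) {
    gamma_traj[[ri]] <- matrix(NA_real_, length(test_pos[[ri]]), K,
                               dimnames = list(reliable[test_pos[[ri]]], NULL))
    if (object$history) endo_traj[[ri]] <- gamma_traj[[ri]]
  }
  red_state <- stats::setNames(vector("list", length(r_run)), r_run)
  D <- raw <- sumg <- lwF <- lwR <- matrix(NA_real_, length(r_run), K,
                                           dimnames = list(r_run, NULL))
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * W + 1L):(k * W)
    wtable_update(tab, if (object$history) object$X[idx, , drop = FALSE],
                  object$o[idx], beta)
    if (k %% 100L == 0L) wtable_compact(tab)
    full <- window_params(object, k)
    llF <- object$ll_beta[k]
    dF <- object$d[k]
    Xw <- if (object$history) object$X[idx, , drop = FALSE] else NULL
    prF <- NULL
    for (ri in as.character(r_run)) {
      pos <- test_pos[[ri]]
      Mi <- length(pos)
      # full-model log-odds of the tested marks over the window's bins
      u <- matrix(rep(full$mu[pos], each = length(idx)), length(idx), Mi)
      if (object$history && nrow(full$support))
        u <- u + Xw %*% full$theta[, pos, drop = FALSE]
      prev <- red_state[[ri]]
      ref <- if (gamma_source == "full" || is.null(prev)) full else prev
      mu_red <- full$mu
      theta_red <- full$theta
      for (pass in seq_len(max(inner_iter, 1L))) {
        P0 <- if (object$history) {
          cpp_mnl_probs(Xw, ref$mu, ref$theta)[, -1L, drop = FALSE]
        } else {
          matrix(drop(event_probs(NULL, mkpp_params(ref$mu, marks = reliable))$p_mark),
                 length(idx), M_all, byrow = TRUE)
        }
        u0 <- indep_log_odds(P0, patt, pos)
        g_hat <- exogenous_factor(u, u0)
        mu_red <- full$mu
        mu_red[pos] <- full$mu[pos] - g_hat
        if (!is.null(prev)) {
          # warm-start free coordinates at the previous reduced solution
          mu_red[-pos] <- prev$mu[-pos]
          theta_red <- prev$theta
        }
        fitR <- fit_mnl(tab, mu_red, theta_red, full$support,
                        free_mu = !(seq_len(M_all) %in% pos),
                        tol = object$settings$tol,
                        max_iter = object$settings$max_iter,
                        mu_floor = object$settings$mu_floor,
                        ridge = object$settings$ridge)
        ref <- list(mu = fitR$mu, theta = fitR$theta)
        if (pass < inner_iter) next
      }
      red_state[[ri]] <- list(mu = fitR$mu, theta = fitR$theta)
      llR <- fitR$loglik
      dR <- dF - Mi
      if (bias == "support") {
        D[ri, k] <- deviance_difference(llF, llR, beta,
                                        bias_estimate(dF, beta),
                                        bias_estimate(dR, beta))
      } else if (bias == "plugin") {
        tr_term <- pin_bias_term(wtable_view(tab), full, pos, Xw, patt,
                                 object$settings$ridge)
        D[ri, k] <- deviance_difference(llF, llR, beta) - (tr_term - Mi)
      } else {
        D[ri, k] <- deviance_difference(llF, llR, beta)
      }
      raw[ri, k] <- 2 * (llF - llR)
      # the net exogenous sign sums only marks with current evidence: a mark
      # whose base rate sits at the numerical floor has had no recent events
      # and its fitted log-odds (hence gamma_hat) reflect the floor, not data
      lively <- full$mu[pos] > object$settings$mu_floor + 1e-6
      mseq <- ms$marks[idx]
      parF <- mkpp_params(full$mu, full$theta, marks = reliable)
      parR <- mkpp_params(fitR$mu, fitR$theta, marks = reliable)
      lwF[ri, k] <- window_loglik(mseq, Xw, parF)
      lwR[ri, k] <- window_loglik(mseq, Xw, parR)
      sumg[ri, k] <- sum(g_hat[lively])
      gamma_traj[[ri]][, k] <- g_hat
      if (object$history)
        endo_traj[[ri]][, k] <- colMeans(Xw %*% full$theta[, pos, drop = FALSE])
    }
  }
  # rejection decisions (optionally BH-corrected across orders per window)
  h <- matrix(0, length(r_run), K, dimnames = list(r_run, NULL))
  for (k in seq_len(K)) {
    pv <- vapply(as.character(r_run), function(ri)
      stats::pchisq(D[ri, k], df = length(test_pos[[ri]]), lower.tail = FALSE),
      numeric(1))
    if (p_adjust == "BH") pv <- stats::p.adjust(pv, "BH")
    for (ri in as.character(r_run))
      if (!is.na(pv[ri]) && pv[ri] < alpha)
        h[ri, k] <- { s <- sign(sumg[ri, k]); if (s == 0) 1 else s }
  }
  nu <- J <- matrix(NA_real_, length(r_run), K, dimnames = list(r_run, NULL))
  for (ri in as.character(r_run)) {
    Mi <- length(test_pos[[ri]])
    sm <- smooth_noncentrality(D[ri, ], Mi)
    nu[ri, ] <- sm$nu
    J[ri, ] <- j_statistic(sm$nu, Mi, alpha, h[ri, ])
  }
  results <- do.call(rbind, lapply(as.character(r_run), function(ri)
    data.frame(window = seq_len(K),
               time_start = ((seq_len(K) - 1L) * W) * ms$bin_size,
               r = as.integer(ri),
               D = D[ri, ], raw_dev = raw[ri, ],
               ll_win_full = lwF[ri, ], ll_win_red = lwR[ri, ],
               nu_hat = nu[ri, ], h = h[ri, ], J = J[ri, ],
               sum_gamma = sumg[ri, ])))
  rownames(results) <- NULL
  structure(list(
    results = results,
    gamma = gamma_traj,
    endo = if (object$history) endo_traj,
    M = stats::setNames(lengths(test_pos[as.character(r_run)]), r_run),
    marks_tested = lapply(test_pos[as.character(r_run)],
                          function(p) reliable[p]),
    skipped = skipped,
    alpha = alpha, W = W, beta = beta, history = object$history,
    bias = bias, bin_size = ms$bin_size, K = K,
    call = match.call()
  ), class = "coord_test")
}

#' @export
print.coord_test <- function(x, ...) {
  cat(sprintf("rth-order coordination test: %d windows, alpha = %g, beta = %g, W = %d\n",
              x$K, x$alpha, x$beta, x$W))
  cat(sprintf("  model: %s; bias estimator: %s\n",
              if (x$history) "history-dependent" else "history-independent",
              x$bias))
  for (ri in names(x$M)) {
    sub <- x$results[x$results$r == as.integer(ri), ]
    cat(sprintf("  r = %s (M = %d): rejected %d/%d windows (%d facilitation, %d suppression); median D = %.1f\n",
                ri, x$M[[ri]], sum(sub$h != 0), nrow(sub),
                sum(sub$h > 0), sum(sub$h < 0),
                stats::median(sub$D, na.rm = TRUE)))
  }
  if (length(x$skipped))
    cat("  skipped orders (no reliable marks):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.coord_test <- function(object, ...) {
  s <- lapply(names(object$M), function(ri) {
    sub <- object$results[object$results$r == as.integer(ri), ]
    data.frame(r = as.integer(ri), M = object$M[[ri]],
               windows = nrow(sub),
               rejected = sum(sub$h != 0),
               rejection_rate = mean(sub$h != 0),
               mean_D = mean(sub$D, na.rm = TRUE),
               max_abs_J = max(abs(sub$J), na.rm = TRUE))
  })
  out <- do.call(rbind, s)
  class(out) <- c("summary.coord_test", "data.frame")
  out
}

#' Plot the signed J-statistic trajectories
#'
#' @param x a `coord_test`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coord_test <- function(x, ...) {
  rs <- sort(unique(x$results$r))
  cols <- grDevices::hcl.colors(max(length(rs), 2L), "Dark 3")
  first <- TRUE
  for (i in seq_along(rs)) {
    sub <- x$results[x$results$r == rs[i], ]
    if (first) {
      graphics::plot(sub$time_start, sub$J, type = "s", col = cols[i],
                     ylim = c(-1, 1), xlab = "time (s)",
                     ylab = "signed J-statistic", ...)
      graphics::abline(h = 0, lty = 3)
      first <- FALSE
    } else {
      graphics::lines(sub$time_start, sub$J, type = "s", col = cols[i])
    }
  }
  graphics::legend("topright", legend = paste0("r = ", rs),
                   col = cols[seq_along(rs)], lty = 1, bty = "n")
  invisible(x)
}
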