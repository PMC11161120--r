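# Sequential maximum-likelihood estimation over windows with a forgetting
# factor. The weighted window log-likelihood
#   l_k^beta(w) = (1 - beta) * sum_{i<=k} beta^(k-i) l_i(w)
# is maintained exactly as a table of distinct covariate rows with
# per-outcome weights updated by  w <- beta * w + (1 - beta) * counts_k,
# which is an exact compression for the categorical GLM (the log-likelihood
# depends on the data only through how often each (covariate row, outcome)
# pair occurs). The history-dependent model is fit per window by greedy
# orthogonal matching pursuit over (mark, covariate) pairs with damped-Newton
# refits; the history-independent model has a closed-form weighted MLE.

# ---- weighted data table ---------------------------------------------------

new_wtable <- function(p, M) {
  env <- new.env(parent = emptyenv())
  env$p <- as.integer(p)
  env$M <- as.integer(M)
  env$n <- 0L
  env$cap <- 64L
  env$X <- matrix(0, 64L, p)
  env$Wt <- matrix(0, 64L, M + 1L)
  env$hash <- new.env(hash = TRUE, parent = emptyenv())
  env
}

wtable_key <- function(row) intToUtf8(row + 65L)

wtable_update <- function(tab, Xw, o_w, beta) {
  n <- tab$n
  if (n) tab$Wt[seq_len(n), ] <- tab$Wt[seq_len(n), ] * beta
  inc <- 1 - beta
  nb <- length(o_w)
  for (i in seq_len(nb)) {
    key <- if (tab$p) wtable_key(Xw[i, ]) else "."
    idx <- tab$hash[[key]]
    if (is.null(idx)) {
      if (tab$n == tab$cap) {
        tab$cap <- tab$cap * 2L
        Xn <- matrix(0, tab$cap, tab$p); Xn[seq_len(tab$n), ] <- tab$X[seq_len(tab$n), ]
        Wn <- matrix(0, tab$cap, tab$M + 1L); Wn[seq_len(tab$n), ] <- tab$Wt[seq_len(tab$n), ]
        tab$X <- Xn; tab$Wt <- Wn
      }
      tab$n <- tab$n + 1L
      idx <- tab$n
      if (tab$p) tab$X[idx, ] <- Xw[i, ]
      tab$hash[[key]] <- idx
    }
    tab$Wt[idx, o_w[i] + 1L] <- tab$Wt[idx, o_w[i] + 1L] + inc
  }
  invisible(tab)
}

# drop rows whose residual weight is numerically negligible
wtable_compact <- function(tab, floor = 1e-10) {
  n <- tab$n
  if (!n) return(invisible(tab))
  keep <- which(rowSums(tab$Wt[seq_len(n), , drop = FALSE]) >= floor)
  if (length(keep) == n) return(invisible(tab))
  tab$X[seq_along(keep), ] <- tab$X[keep, ]
  tab$Wt[seq_along(keep), ] <- tab$Wt[keep, ]
  tab$n <- length(keep)
  tab$hash <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(tab$n))
    tab$hash[[if (tab$p) wtable_key(tab$X[i, ]) else "."]] <- i
  invisible(tab)
}

wtable_view <- function(tab) {
  list(X = tab$X[seq_len(tab$n), , drop = FALSE],
       Wt = tab$Wt[seq_len(tab$n), , drop = FALSE])
}

wtable_clone <- function(tab) {
  env <- new.env(parent = emptyenv())
  for (nm in c("p", "M", "n", "cap", "X", "Wt")) assign(nm, get(nm, tab), env)
  env$hash <- new.env(hash = TRUE, parent = emptyenv())
  for (key in ls(tab$hash)) env$hash[[key]] <- tab$hash[[key]]
  env
}

# ---- Newton refit on a fixed coordinate set --------------------------------

# coords: free base rates (cov = 0) for marks where free_mu is TRUE, plus the
# supported theta entries. Parameters are box-constrained (base rates floored
# at mu_floor, couplings capped at +/- theta_cap): under sparse weighted data
# a covariate can perfectly predict a rare mark (quasi-separation), in which
# case the unconstrained MLE is infinite. Convergence is assessed by the KKT
# conditions: the projected gradient must be below tol, i.e. coordinates
# pressed against a bound may keep a one-sided gradient.
fit_mnl <- function(tab, mu, theta, support, free_mu,
                    tol = 1e-6, max_iter = 200L, mu_floor = -25,
                    theta_cap = 15, ridge = 0) {
  v <- wtable_view(tab)
  ns <- nrow(support)
  d_mu <- which(free_mu)
  nmu <- length(d_mu)
  coord_mark <- as.integer(c(d_mu, if (ns) support[, 1L]))
  coord_cov <- as.integer(c(rep(0L, nmu), if (ns) support[, 2L]))
  sup_idx <- if (ns) cbind(support[, 2L], support[, 1L])
  mu_cap <- 10
  # re-seed floored base rates that have since accrued weight: the closed-form
  # marginal log-odds is a far better start than the floor, where the Newton
  # model is hopelessly flat
  if (nmu) {
    w <- colSums(v$Wt)
    w0 <- max(w[1L], 1e-300)
    reseed <- d_mu[mu[d_mu] <= mu_floor + 1e-9 & w[d_mu + 1L] > 1e-12]
    if (length(reseed))
      mu[reseed] <- pmin(pmax(log(w[reseed + 1L] / w0), mu_floor), mu_cap)
  }
  # objective: l_k^beta - ridge/2 * ||theta||^2 (the penalty regularizes
  # quasi-separated couplings; it is common to the full and reduced fits)
  pen_of <- function(ev, theta) {
    ev$loglik - if (ns && ridge > 0) ridge / 2 * sum(theta[sup_idx]^2) else 0
  }
  pick_g <- function(ev, theta) {
    c(if (nmu) ev$gmu[d_mu],
      if (ns) ev$gtheta[sup_idx] - ridge * theta[sup_idx])
  }
  kkt_g <- function(g, mu, theta) {
    # zero out gradient components pointing outward at an active bound
    if (nmu) {
      gm <- g[seq_len(nmu)]
      gm[mu[d_mu] <= mu_floor & gm < 0] <- 0
      gm[mu[d_mu] >= mu_cap & gm > 0] <- 0
      g[seq_len(nmu)] <- gm
    }
    if (ns) {
      th <- theta[sup_idx]
      gi <- g[nmu + seq_len(ns)]
      gi[th >= theta_cap & gi > 0] <- 0
      gi[th <= -theta_cap & gi < 0] <- 0
      g[nmu + seq_len(ns)] <- gi
    }
    g
  }
  step_to <- function(mu, theta, delta, step) {
    if (nmu)
      mu[d_mu] <- pmin(pmax(mu[d_mu] + step * delta[seq_len(nmu)], mu_floor),
                       mu_cap)
    if (ns)
      theta[sup_idx] <- pmin(pmax(theta[sup_idx] +
                                    step * delta[nmu + seq_len(ns)],
                                  -theta_cap), theta_cap)
    list(mu = mu, theta = theta)
  }
  ev <- cpp_mnl_eval(v$X, v$Wt, mu, theta, TRUE)
  ll <- pen_of(ev, theta)
  converged <- length(coord_mark) == 0L
  it <- 0L
  stalled <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    g <- kkt_g(pick_g(ev, theta), mu, theta)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    # active set: coordinates pressed against a bound (zeroed KKT gradient)
    # stay fixed this iteration; Newton runs on the free coordinates only
    free <- g != 0
    Hf <- cpp_mnl_hess(v$X, v$Wt, mu, theta, coord_mark[free], coord_cov[free])
    A <- -Hf
    if (ridge > 0) {
      ridge_diag <- as.numeric(coord_cov[free] > 0L) * ridge
      diag(A) <- diag(A) + ridge_diag
    }
    base <- max(diag(A), 1)
    accepted <- FALSE
    lambda <- 1e-9
    while (!accepted && lambda < 1e3) {
      df <- tryCatch(solve(A + diag(lambda * base, nrow(A)), g[free]),
                     error = function(e) NULL)
      if (!is.null(df)) {
        # per-coordinate trust region: flat directions (tiny curvature from
        # near-zero event weight) otherwise produce wild steps on the
        # log-odds scale that backtracking must grind down
        delta <- numeric(length(g))
        delta[free] <- pmin(pmax(df, -4), 4)
        step <- 1
        for (half in 1:20) {
          cand <- step_to(mu, theta, delta, step)
          ev2 <- cpp_mnl_eval(v$X, v$Wt, cand$mu, cand$theta, TRUE)
          ll2 <- pen_of(ev2, cand$theta)
          if (ll2 > ll) { accepted <- TRUE; break }
          step <- step / 2
        }
      }
      lambda <- lambda * 1e3  # Levenberg-style damping on failure
    }
    if (!accepted) break
    if (ll2 - ll < 1e-12) stalled <- stalled + 1L else stalled <- 0L
    mu <- cand$mu; theta <- cand$theta; ll <- ll2; ev <- ev2
    if (stalled >= 2L) {
      converged <- max(abs(kkt_g(pick_g(ev, theta), mu, theta))) < tol
      break
    }
  }
  if (!converged && it > 0L)
    converged <- max(abs(kkt_g(pick_g(ev, theta), mu, theta))) < tol
  list(mu = mu, theta = theta, loglik = ll, raw_loglik = ev$loglik,
       converged = converged, iter = it)
}

# One AdOMP window: refit the warm-started support, then greedily add the
# (mark, covariate) pair with the largest absolute gradient, refit all
# supported coordinates, and stop when a mark's budget is exhausted or the
# log-likelihood gain falls below gain_tol. Ties resolve to the lowest mark
# index, then the lowest lag (column-major first maximum over the lag-major
# covariate ordering).
adomp_window <- function(tab, mu, theta, support, free_mu, s,
                         tol = 1e-6, max_iter = 200L, mu_floor = -25,
                         gain_tol = 1e-6, ridge = 0) {
  fit <- fit_mnl(tab, mu, theta, support, free_mu, tol, max_iter, mu_floor,
                 ridge = ridge)
  M <- length(mu)
  p <- nrow(theta)
  if (s > 0L && p > 0L) {
    v <- wtable_view(tab)
    repeat {
      if (nrow(support) >= s * M) break
      ev <- cpp_mnl_eval(v$X, v$Wt, fit$mu, fit$theta, TRUE)
      G <- abs(ev$gtheta)
      if (nrow(support)) {
        G[cbind(support[, 2L], support[, 1L])] <- -Inf
        at_budget <- tabulate(support[, 1L], nbins = M) >= s
        if (any(at_budget)) G[, at_budget] <- -Inf
      }
      j <- which.max(G)
      if (!is.finite(G[j]) || G[j] < tol) break
      mk <- (j - 1L) %/% p + 1L
      cv <- (j - 1L) %% p + 1L
      cand <- rbind(support, c(mk, cv))
      fit2 <- fit_mnl(tab, fit$mu, fit$theta, cand, free_mu,
                      tol, max_iter, mu_floor, ridge = ridge)
      if (fit2$loglik - fit$loglik < gain_tol) break
      support <- cand
      fit <- fit2
    }
  }
  fit$support <- support
  fit
}

# closed-form weighted MLE of the intercept-only (history-independent) model
hf_closed_form <- function(tab, mu_floor = -25) {
  v <- wtable_view(tab)
  w <- colSums(v$Wt)
  w0 <- max(w[1L], 1e-300)
  pmax(log(pmax(w[-1L], 1e-300) / w0), mu_floor)
}

# ---- the fitting function --------------------------------------------------

#' Fit an adaptive marked point-process model of ensemble spiking
#'
#' Fits the discretized marked point-process multinomial GLM over
#' non-overlapping windows of `W` bins by sequential maximum likelihood with
#' forgetting factor `beta`: window k maximizes the exponentially weighted
#' log-likelihood `(1-beta) * sum_i beta^(k-i) l_i`. With `history = TRUE`
#' the log-odds of each reliable mark include sparse couplings to the raw
#' binary lags (1..L) of every neuron's spike train, selected per window by
#' adaptive orthogonal matching pursuit (greedy largest-gradient selection
#' with full refits, warm-started from the previous window); with
#' `history = FALSE` only the base rates are fit (closed-form weighted MLE).
#'
#' @param x a [spike_ensemble].
#' @param W window length in bins over which parameters are constant.
#' @param beta forgetting factor in `[0, 1)`; the effective integration
#'   window is about `W / (1 - beta)` bins.
#' @param history logical: include ensemble spiking-history covariates?
#' @param L history integration window (number of lags) when `history`.
#' @param basis history basis passed to [history_covariates()].
#' @param N_thr pruning threshold passed to [mark_space()].
#' @param sparsity maximum number of history couplings per mark selected by
#'   the greedy pass; default `max(ceiling(0.1 * C * L), C)` — at least one
#'   coupling per neuron, since a mark's history dependence is a sum of its
#'   member neurons' couplings.
#' @param tol gradient sup-norm convergence tolerance of the Newton refits.
#' @param max_iter maximum Newton iterations per refit.
#' @param mu_floor lower bound on base-rate parameters (log-odds).
#' @param gain_tol greedy selection stops when the weighted log-likelihood
#'   gain of the candidate falls below this.
#' @param ridge small quadratic penalty on the history couplings
#'   (objective `l_k^beta - ridge/2 * ||theta||^2`). It regularizes
#'   quasi-separated couplings (a covariate that happens to precede every
#'   event of a rare mark would otherwise be driven to infinity) and is
#'   applied identically to full and reduced fits, so it cancels from the
#'   deviance under the null. Set to 0 for the pure maximum-likelihood
#'   greedy fit.
#' @return An object of class `mkpp_fit`: per-window base rates (`mu`, a
#'   `M x K` matrix), per-window history-coupling supports and values
#'   (`theta_traj`), weighted log-likelihoods (`ll_beta`), support
#'   cardinalities (`d`), and the underlying [mark_space]. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `residuals`,
#'   `simulate`, `confint`.
#' @examples
#' sc <- scenario_step(n_realizations = 1, T = 600, seed = 1)[[1]]
#' fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.95, history = FALSE)
#' fit
#' @export
mkpp_fit <- function(x, W = 10L, beta = 0.99, history = TRUE, L = 5L,
                     N_thr = 1L, sparsity = NULL, tol = 1e-6,
                     max_iter = 200L, mu_floor = -25, gain_tol = 1e-6,
                     ridge = 0.01, basis = c("raw", "log")) {
  stopifnot(inherits(x, "spike_ensemble"))
  if (W < 1L) stop("'W' must be >= 1")
  if (beta < 0 || beta >= 1) stop("'beta' must be in [0, 1)")
  ms <- mark_space(x, N_thr)
  M <- length(ms$reliable)
  if (M == 0L)
    stop("no reliable marks: every observed pattern occurs at most N_thr times")
  T_ <- length(ms$marks)
  K <- T_ %/% W
  if (K < 1L) stop("fewer bins than one window")
  o <- outcome_index(ms$marks, ms$reliable)
  X <- if (history) history_covariates(x, L, basis = match.arg(basis))
       else NULL
  p <- if (history) ncol(X) else 0L
  C_ <- nrow(x$counts)
  if (is.null(sparsity)) sparsity <- max(ceiling(0.1 * p), C_)
  tab <- new_wtable(p, M)
  mu_traj <- matrix(NA_real_, M, K)
  theta_traj <- vector("list", K)
  ll_beta <- d_traj <- numeric(K)
  conv <- logical(K)
  mu <- rep(mu_floor, M)
  theta <- matrix(0, p, M)
  support <- matrix(integer(), 0L, 2L)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * W + 1L):(k * W)
    wtable_update(tab, if (history) X[idx, , drop = FALSE], o[idx], beta)
    if (k %% 100L == 0L) wtable_compact(tab)
    if (!history) {
      mu <- hf_closed_form(tab, mu_floor)
      v <- wtable_view(tab)
      ll_beta[k] <- cpp_mnl_eval(v$X, v$Wt, mu, theta, FALSE)$loglik
      conv[k] <- TRUE
    } else {
      if (k == 1L) mu <- hf_closed_form(tab, mu_floor)
      fit <- adomp_window(tab, mu, theta, support, rep(TRUE, M), sparsity,
                          tol, max_iter, mu_floor, gain_tol, ridge)
      mu <- fit$mu; theta <- fit$theta; support <- fit$support
      ll_beta[k] <- fit$loglik
      conv[k] <- fit$converged
      theta_traj[[k]] <- list(support = support,
                              values = if (nrow(support))
                                theta[cbind(support[, 2L], support[, 1L])]
                              else numeric(0))
    }
    mu_traj[, k] <- mu
    d_traj[k] <- M + nrow(support)
  }
  if (!all(conv))
    warning(sprintf("%d of %d windows did not reach gradient tolerance; best iterates kept",
                    sum(!conv), K))
  structure(list(
    mark_space = ms, X = X, o = o, W = as.integer(W), beta = beta, K = K,
    history = history, L = if (history) as.integer(L) else NA_integer_,
    p = p, sparsity = sparsity,
    mu = mu_traj, theta_traj = theta_traj, ll_beta = ll_beta, d = d_traj,
    converged = conv, table = tab,
    settings = list(tol = tol, max_iter = max_iter, mu_floor = mu_floor,
                    gain_tol = gain_tol, N_thr = N_thr, ridge = ridge),
    call = match.call()
  ), class = "mkpp_fit")
}

#' Forgetting-factor weighted log-likelihood (direct definition)
#'
#' Evaluates `(1 - beta) * sum_{i=1}^{k} beta^(k-i) l_i(params)` by direct
#' summation over the window log-likelihoods, all evaluated at a common
#' parameter value. The adaptive fitter maintains the same quantity through
#' an exact recursive compression; this direct form is the reference.
#'
#' @param params an [mkpp_params].
#' @param marks_seq outcome sequence over all bins (`{0} U params$marks`).
#' @param X covariate matrix over all bins, or NULL.
#' @param W window length in bins.
#' @param beta forgetting factor in `[0, 1)`.
#' @param k evaluate at this window (default: last complete window).
#' @return Scalar weighted log-likelihood.
#' @export
weighted_loglik <- function(params, marks_seq, X = NULL, W, beta, k = NULL) {
  K <- length(marks_seq) %/% W
  if (is.null(k)) k <- K
  stopifnot(k >= 1L, k <= K)
  ll <- 0
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * W + 1L):(i * W)
    ll <- ll + beta^(k - i) *
      window_loglik(marks_seq[idx], if (!is.null(X)) X[idx, , drop = FALSE],
                    params)
  }
  (1 - beta) * ll
}

# rebuild the weighted table as it stood after window k
replay_table <- function(object, k) {
  tab <- new_wtable(object$p, length(object$mark_space$reliable))
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * object$W + 1L):(i * object$W)
    wtable_update(tab,
                  if (object$history) object$X[idx, , drop = FALSE],
                  object$o[idx], object$beta)
    if (i %% 100L == 0L) wtable_compact(tab)
  }
  tab
}

# ---- methods ---------------------------------------------------------------

#' @export
print.mkpp_fit <- function(x, ...) {
  cat(sprintf("Adaptive MkPP model: %d reliable marks, %d windows of %d bins\n",
              nrow(x$mu), x$K, x$W))
  cat(sprintf("  forgetting factor %g (effective window %.0f bins); %s\n",
              x$beta, effective_window(x$W, x$beta),
              if (x$history)
                sprintf("history-dependent (L = %d, budget %d/mark)",
                        x$L, x$sparsity)
              else "history-independent"))
  cat(sprintf("  final weighted log-likelihood: %.4f; final support size: %d\n",
              x$ll_beta[x$K], x$d[x$K]))
  invisible(x)
}

#' @export
summary.mkpp_fit <- function(object, ...) {
  out <- list(fit = object,
              final = coef(object),
              support_size = object$d,
              ll = object$ll_beta)
  class(out) <- "summary.mkpp_fit"
  out
}

#' @export
print.summary.mkpp_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFinal-window base rates (log-odds vs no event):\n")
  print(round(stats::setNames(x$final$mu, x$final$marks), 3))
  if (nrow(x$final$support)) {
    cat("\nSelected history couplings (final window):\n")
    sup <- x$final$support
    df <- data.frame(mark = x$final$marks[sup[, 1L]],
                     covariate = rownames(x$final$theta)[sup[, 2L]],
                     value = x$final$theta[cbind(sup[, 2L], sup[, 1L])])
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Extract per-window model parameters
#'
#' @param object an `mkpp_fit`.
#' @param window window index (default: last).
#' @param ... unused.
#' @return An [mkpp_params] for that window.
#' @export
coef.mkpp_fit <- function(object, window = object$K, ...) {
  stopifnot(window >= 1L, window <= object$K)
  M <- nrow(object$mu)
  theta <- matrix(0, object$p, M)
  if (object$p)
    rownames(theta) <- colnames(object$X)
  sup <- matrix(integer(), 0L, 2L)
  if (object$history && !is.null(object$theta_traj[[window]])) {
    tt <- object$theta_traj[[window]]
    sup <- tt$support
    if (nrow(sup)) theta[cbind(sup[, 2L], sup[, 1L])] <- tt$values
  }
  mkpp_params(object$mu[, window], theta, marks = object$mark_space$reliable,
              support = sup)
}

#' @export
logLik.mkpp_fit <- function(object, window = object$K, ...) {
  structure(object$ll_beta[window], df = object$d[window],
            class = "logLik")
}

#' Per-bin event probabilities from a fitted model
#'
#' @param object an `mkpp_fit`.
#' @param type `"prob"` for per-bin categorical probabilities (columns:
#'   `none`, then one per reliable mark) or `"log_odds"` for `u_t(m)`.
#' @param ... unused.
#' @return T x (M+1) matrix (`"prob"`) or T x M matrix (`"log_odds"`), each
#'   bin evaluated at its own window's parameters (trailing bins beyond the
#'   last complete window use the final window).
#' @export
predict.mkpp_fit <- function(object, type = c("prob", "log_odds"), ...) {
  type <- match.arg(type)
  T_ <- length(object$o)
  M <- nrow(object$mu)
  win <- pmin((seq_len(T_) - 1L) %/% object$W + 1L, object$K)
  out <- matrix(NA_real_, T_, if (type == "prob") M + 1L else M)
  for (k in unique(win)) {
    rows <- which(win == k)
    par <- coef(object, k)
    Xk <- if (object$history) object$X[rows, , drop = FALSE] else NULL
    if (type == "prob") {
      pr <- event_probs(Xk, par)
      if (is.null(Xk)) {
        out[rows, 1L] <- pr$p_none
        out[rows, -1L] <- matrix(pr$p_mark, length(rows), M, byrow = TRUE)
      } else {
        out[rows, ] <- cbind(pr$p_none, pr$p_mark)
      }
    } else {
      U <- vapply(par$marks, function(m) {
        u <- log_odds(Xk, par, m)
        if (length(u) == 1L) rep(u, length(rows)) else u
      }, numeric(length(rows)))
      out[rows, ] <- U
    }
  }
  colnames(out) <- if (type == "prob") c("none", object$mark_space$reliable)
                   else as.character(object$mark_space$reliable)
  out
}

#' @export
residuals.mkpp_fit <- function(object, ...) {
  P <- predict(object, type = "prob")
  M <- nrow(object$mu)
  Y <- matrix(0, length(object$o), M)
  nz <- object$o > 0L
  Y[cbind(which(nz), object$o[nz])] <- 1
  R <- Y - P[, -1L, drop = FALSE]
  colnames(R) <- as.character(object$mark_space$reliable)
  R
}

#' Simulate new spiking data from a fitted model
#'
#' Draws a fresh marked sequence from the categorical model at a chosen
#' window's parameters (history couplings feed back on the simulated spiking).
#'
#' @param object an `mkpp_fit`.
#' @param nsim number of realizations.
#' @param seed integer seed.
#' @param window window whose parameters generate the data.
#' @param nbins length of each realization in bins.
#' @param ... unused.
#' @return List of [spike_ensemble] objects.
#' @export
simulate.mkpp_fit <- function(object, nsim = 1, seed = NULL,
                              window = object$K,
                              nbins = length(object$o), ...) {
  par <- coef(object, window)
  C <- object$mark_space$n_neurons
  lapply(seq_len(nsim), function(i) {
    simulate_ensemble(C = C, nbins = nbins, params = par,
                      L = if (object$history) object$L else 1L,
                      bin_size = object$mark_space$bin_size,
                      seed = if (!is.null(seed)) seed + i - 1L)$spikes
  })
}

# ---- de-sparsified estimates and confidence intervals ----------------------

#' De-sparsified parameter estimates with confidence intervals
#'
#' One-step de-biasing of the greedy estimate at a window:
#' `w_tilde = w_hat + I(w_hat)^{-1} grad l_k^beta(w_hat)`, restricted to the
#' fitted coordinate set (`relaxation = "support"`: all base rates plus the
#' selected history couplings) or to every coordinate
#' (`relaxation = "full"`). Normal confidence intervals use the
#' observed-information variance scaled by `(1 - beta) / (1 + beta)`. At an
#' interior maximum over the fitted support the de-biasing is a no-op there;
#' it corrects coordinates excluded by the greedy selection.
#'
#' @param object an `mkpp_fit`.
#' @param window window index (default: last).
#' @param level confidence level.
#' @param relaxation `"support"` or `"full"`.
#' @return Data frame with one row per coordinate: `mark`, `covariate`
#'   (`"(base rate)"` for mu), `estimate`, `debiased`, `se`, `lower`,
#'   `upper`.
#' @export
desparsify <- function(object, window = object$K, level = 0.95,
                       relaxation = c("support", "full")) {
  relaxation <- match.arg(relaxation)
  stopifnot(inherits(object, "mkpp_fit"))
  tab <- if (window == object$K) object$table else replay_table(object, window)
  par <- coef(object, window)
  M <- length(par$mu)
  if (relaxation == "full" && object$p > 0L) {
    coord_mark <- c(seq_len(M), rep(seq_len(M), each = object$p))
    coord_cov <- c(rep(0L, M), rep(seq_len(object$p), M))
  } else {
    sup <- par$support
    coord_mark <- c(seq_len(M), if (nrow(sup)) sup[, 1L])
    coord_cov <- c(rep(0L, M), if (nrow(sup)) sup[, 2L])
  }
  v <- wtable_view(tab)
  ev <- cpp_mnl_eval(v$X, v$Wt, par$mu, par$theta, TRUE)
  g <- ifelse(coord_cov == 0L, ev$gmu[coord_mark],
              ev$gtheta[cbind(pmax(coord_cov, 1L), coord_mark)])
  H <- cpp_mnl_hess(v$X, v$Wt, par$mu, par$theta,
                    as.integer(coord_mark), as.integer(coord_cov))
  A <- -H
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    warning("singular observed information; ridge-regularized inverse used")
    Ainv <- solve(A + diag(1e-6 * max(diag(A), 1), nrow(A)))
  }
  est <- ifelse(coord_cov == 0L, par$mu[coord_mark],
                par$theta[cbind(pmax(coord_cov, 1L), coord_mark)])
  deb <- est + drop(Ainv %*% g)
  se <- sqrt(pmax(diag(Ainv), 0) * (1 - object$beta) / (1 + object$beta))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    mark = object$mark_space$reliable[coord_mark],
    covariate = ifelse(coord_cov == 0L, "(base rate)",
                       if (object$p) colnames(object$X)[pmax(coord_cov, 1L)]
                       else "(base rate)"),
    estimate = est, debiased = deb, se = se,
    lower = deb - z * se, upper = deb + z * se,
    stringsAsFactors = FALSE
  )
}

#' @export
confint.mkpp_fit <- function(object, parm = "mu", level = 0.95, ...) {
  df <- desparsify(object, level = level, ...)
  if (identical(parm, "mu")) df <- df[df$covariate == "(base rate)", ]
  out <- as.matrix(df[, c("lower", "upper")])
  rownames(out) <- paste0(ifelse(df$covariate == "(base rate)", "mu", "theta"),
                          "[", df$mark,
                          ifelse(df$covariate == "(base rate)", "",
                                 paste0(",", df$covariate)), "]")
  out
}
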