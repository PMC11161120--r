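# The discretized marked point-process likelihood: a multinomial logistic
# GLM over {no event} U reliable marks, optionally with ensemble spiking
# history covariates. The log-odds of mark m versus no event are
#   u_t(m) = mu(m) + x_t' theta(m),
# reducing to the history-independent model u_t(m) = mu(m) when theta = 0.

#' Ensemble spiking-history covariates
#'
#' Builds the history basis over bins strictly before t. The default
#' (`basis = "raw"`) uses the raw binary lags 1..L of each neuron's spike
#' train, lag-major (all neurons at lag 1, then lag 2, ...), giving
#' p = C*L columns named `c<neuron>.l<lag>`. With `basis = "log"` lags are
#' grouped into log-spaced windows (1, 2, 3-4, 5-8, ... up to L) and each
#' covariate indicates any spike of that neuron within the window, which
#' covers long histories with few columns.
#'
#' @param x a [spike_ensemble].
#' @param L history integration window in bins (deepest lag).
#' @param basis `"raw"` or `"log"`.
#' @return T x p binary matrix with a `lags` attribute.
#' @export
history_covariates <- function(x, L = 5L, basis = c("raw", "log")) {
  stopifnot(inherits(x, "spike_ensemble"), L >= 1L)
  basis <- match.arg(basis)
  C <- nrow(x$counts)
  T_ <- ncol(x$counts)
  raw <- matrix(0, nrow = T_, ncol = C * L)
  for (l in seq_len(L)) {
    cols <- (l - 1L) * C + seq_len(C)
    if (T_ > l)
      raw[(l + 1L):T_, cols] <- t(x$counts[, 1L:(T_ - l), drop = FALSE])
  }
  if (basis == "raw") {
    colnames(raw) <- paste0("c", rep(seq_len(C), L),
                            ".l", rep(seq_len(L), each = C))
    attr(raw, "lags") <- L
    return(raw)
  }
  # log-spaced lag windows: 1, 2, 3-4, 5-8, ..., truncated at L
  lo <- 1L
  groups <- list()
  width <- 1L
  while (lo <= L) {
    hi <- min(lo + width - 1L, L)
    groups[[length(groups) + 1L]] <- lo:hi
    lo <- hi + 1L
    if (length(groups) >= 2L) width <- width * 2L
  }
  X <- matrix(0, nrow = T_, ncol = C * length(groups))
  nms <- character(ncol(X))
  for (g in seq_along(groups)) {
    cols <- (g - 1L) * C + seq_len(C)
    block <- raw[, (min(groups[[g]]) - 1L) * C + seq_len(C), drop = FALSE]
    for (l in groups[[g]][-1L])
      block <- pmax(block, raw[, (l - 1L) * C + seq_len(C), drop = FALSE])
    X[, cols] <- block
    nms[cols] <- paste0("c", seq_len(C), ".l", min(groups[[g]]),
                        if (length(groups[[g]]) > 1L)
                          paste0("_", max(groups[[g]])) else "")
  }
  colnames(X) <- nms
  attr(X, "lags") <- L
  X
}

#' Marked point-process model parameters
#'
#' Base rates `mu` (one per reliable mark, the log-odds intercepts) and
#' history coefficients `theta` (covariates x marks; all-zero columns give
#' the history-independent model). `support` records which theta entries are
#' allowed to be non-zero under greedy estimation.
#'
#' @param mu numeric vector of base-rate parameters, named by mark index.
#' @param theta numeric matrix, `p x length(mu)`, or NULL for the
#'   history-independent model.
#' @param marks integer mark indices (defaults to `names(mu)`).
#' @param support two-column integer matrix of (mark position, covariate)
#'   pairs with non-zero theta entries; defaults to all non-zero entries.
#' @return Object of class `mkpp_params`.
#' @export
mkpp_params <- function(mu, theta = NULL, marks = NULL, support = NULL) {
  if (is.null(marks)) marks <- as.integer(names(mu))
  if (anyNA(marks)) stop("marks must be supplied or mu must be named by mark")
  mu <- as.numeric(mu)
  M <- length(mu)
  if (is.null(theta)) theta <- matrix(0, nrow = 0L, ncol = M)
  theta <- as.matrix(theta)
  if (ncol(theta) != M) stop("theta must have one column per mark")
  if (is.null(support)) {
    nz <- which(theta != 0, arr.ind = TRUE)
    support <- cbind(mark = nz[, 2L], cov = nz[, 1L])
  }
  if (!all(is.finite(mu))) stop("mu must be finite")
  structure(list(mu = mu, theta = theta, marks = as.integer(marks),
                 support = support),
            class = "mkpp_params")
}

#' Log-odds of a mark versus no event
#'
#' @param X history covariate matrix (rows = bins) or NULL for the
#'   history-independent model.
#' @param params an [mkpp_params].
#' @param m mark index; must be one of `params$marks`.
#' @return Numeric vector `u_t(m) = mu(m) + x_t' theta(m)` per row of X (a
#'   single value if X is NULL).
#' @export
log_odds <- function(X, params, m) {
  j <- match(m, params$marks)
  if (is.na(j)) stop(sprintf("mark %d is not in the model's reliable set", m))
  u0 <- params$mu[j]
  if (is.null(X) || nrow(params$theta) == 0L) {
    if (is.null(X)) return(u0)
    return(rep(u0, nrow(X)))
  }
  drop(u0 + X %*% params$theta[, j])
}

#' Per-bin categorical event probabilities
#'
#' Multinomial logistic link with the no-event outcome as reference:
#' `p_m = exp(u_m) / (1 + sum_m' exp(u_m'))`, `p_none = 1 / (1 + sum exp(u))`.
#' Normalization is exact by construction; overflow is guarded by
#' max-subtraction.
#'
#' @inheritParams log_odds
#' @return List with `p_none` (length-n vector) and `p_mark` (n x M matrix,
#'   columns named by mark). With `X = NULL` a single row is returned.
#' @export
event_probs <- function(X, params) {
  M <- length(params$mu)
  if (is.null(X)) X <- matrix(0, nrow = 1L, ncol = max(nrow(params$theta), 0L))
  if (nrow(params$theta) == 0L) {
    U <- matrix(params$mu, nrow = nrow(X), ncol = M, byrow = TRUE)
  } else {
    U <- sweep(X %*% params$theta, 2L, params$mu, "+")
  }
  mx <- pmax(0, apply(U, 1L, max))
  lse <- mx + log(exp(-mx) + rowSums(exp(U - mx)))
  p_mark <- exp(U - lse)
  colnames(p_mark) <- params$marks
  list(p_none = exp(-lse), p_mark = p_mark)
}

# outcome vector: positions of seq marks in the reliable list (0 = no event)
outcome_index <- function(marks_seq, reliable) {
  o <- match(marks_seq, reliable)
  o[is.na(o)] <- 0L
  o
}

#' Window log-likelihood of the marked sequence
#'
#' Sum over bins of the log-probability of the observed outcome (a reliable
#' mark or no event) under the categorical model. Probabilities are floored
#' at 1e-12 before taking logs.
#'
#' @param marks_seq integer outcome sequence over the window's bins, values
#'   in `{0} U params$marks`.
#' @param X covariate rows for the same bins (or NULL).
#' @param params an [mkpp_params].
#' @return Scalar log-likelihood (non-positive).
#' @export
window_loglik <- function(marks_seq, X, params) {
  pr <- event_probs(X, params)
  o <- outcome_index(marks_seq, params$marks)
  if (!is.null(X) && nrow(pr$p_mark) != length(o))
    stop("covariate rows and marked sequence differ in length")
  if (is.null(X) && length(o) > 1L) {
    pr$p_none <- rep(pr$p_none, length(o))
    pr$p_mark <- pr$p_mark[rep(1L, length(o)), , drop = FALSE]
  }
  p <- ifelse(o == 0L, pr$p_none, pr$p_mark[cbind(seq_along(o), pmax(o, 1L))])
  sum(log(pmax(p, 1e-12)))
}

#' Gradient of the window log-likelihood
#'
#' `d l / d mu(m) = sum_t (1[o_t = m] - p_t(m))`;
#' `d l / d theta(m) = sum_t x_t (1[o_t = m] - p_t(m))`.
#'
#' @inheritParams window_loglik
#' @return List with `gmu` (length M) and `gtheta` (p x M; zero-row matrix
#'   for the history-independent model).
#' @export
grad_window_loglik <- function(marks_seq, X, params) {
  M <- length(params$mu)
  o <- outcome_index(marks_seq, params$marks)
  n <- length(o)
  if (is.null(X)) {
    pr <- event_probs(NULL, params)
    Y <- matrix(0, n, M)
    Y[cbind(which(o > 0L), o[o > 0L])] <- 1
    resid <- sweep(Y, 2L, drop(pr$p_mark), "-")
    return(list(gmu = colSums(resid), gtheta = params$theta[0L, , drop = FALSE]))
  }
  pr <- event_probs(X, params)
  Y <- matrix(0, n, M)
  Y[cbind(which(o > 0L), o[o > 0L])] <- 1
  resid <- Y - pr$p_mark
  list(gmu = colSums(resid), gtheta = crossprod(X, resid))
}
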