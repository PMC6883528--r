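#' Call TADs from a directionality-index track
#'
#' Fits a 3-state hidden Markov model (downstream bias, no bias, upstream
#' bias) with single-Gaussian emissions to the DI track by EM, decodes the
#' Viterbi state path, and calls a boundary at every switch from the
#' upstream-bias state to the downstream-bias state (with the convention
#' that positive DI = upstream bias, a domain ends in upstream bias and the
#' next begins in downstream bias). Domains are the intervals between
#' consecutive boundaries.
#'
#' `NA` observations are treated as missing (they constrain the path only
#' through the transition structure).
#'
#' @param di per-bin DI vector (2-Mb window).
#' @param self_prob prior self-transition probability.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list with `boundaries` (bin indices at domain starts),
#'   `domains` (data frame `start_bin`, `end_bin`), and `states`
#'   (per-bin Viterbi state: -1 downstream, 0 none, +1 upstream, NA).
#' @export
call_tads <- function(di, self_prob = 0.9, max_iter = 200L, tol = 1e-6) {
  n <- length(di)
  empty <- list(boundaries = integer(0),
                domains = data.frame(start_bin = integer(0),
                                     end_bin = integer(0)),
                states = rep(NA_integer_, n))
  obs_idx <- which(!is.na(di))
  if (n < 3L || length(obs_idx) < 3L) return(empty)
  if (stats::sd(di[obs_idx]) == 0) return(empty)
  # DI is a chi-square statistic whose tails grow with sequencing depth;
  # fit the HMM on an asinh-compressed scale (sign-preserving, so the
  # upstream/downstream structure is untouched) to keep the Gaussian
  # emissions adequate
  scale0 <- stats::mad(di[obs_idx], center = 0)
  if (scale0 == 0) scale0 <- stats::sd(di[obs_idx])
  x <- asinh(di / scale0)

  # init: outer states at the DI tail sextiles, middle state at no-bias 0
  qs <- stats::quantile(di[obs_idx], c(1 / 6, 0.5, 5 / 6), names = FALSE)
  mu <- c(min(qs[1], 0), 0, max(qs[3], 0))
  sdv <- rep(stats::sd(di[obs_idx]), 3)
  off <- (1 - self_prob) / 2
  A <- matrix(off, 3, 3); diag(A) <- self_prob
  pi0 <- rep(1 / 3, 3)

  dens <- function() {
    # n x 3 emission densities; missing observations contribute 1
    e <- matrix(1, n, 3)
    for (s in 1:3)
      e[obs_idx, s] <- stats::dnorm(x[obs_idx], mu[s], max(sdv[s], 1e-6))
    e
  }

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    e <- dens()
    # forward-backward with scaling
    alpha <- matrix(0, n, 3); beta <- matrix(0, n, 3); cscale <- numeric(n)
    a <- pi0 * e[1, ]
    cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * e[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (A %*% (e[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    xi_num <- matrix(0, 3, 3)
    for (t in 1:(n - 1)) {
      m <- outer(alpha[t, ], e[t + 1, ] * beta[t + 1, ]) * A / cscale[t + 1]
      xi_num <- xi_num + m
    }
    ll <- sum(log(cscale))
    # M step (emissions from observed bins only)
    g_obs <- gam[obs_idx, , drop = FALSE]
    wsum <- colSums(g_obs)
    nonempty <- wsum > 1e-8
    mu_new <- mu
    mu_new[nonempty] <- (colSums(g_obs * x[obs_idx]) / wsum)[nonempty]
    # anchor state identity: state 1 stays downstream-biased (mean <= 0),
    # state 2 no-bias (mean pinned at 0), state 3 upstream-biased
    s0 <- stats::sd(x[obs_idx])
    mu <- c(min(mu_new[1], -0.05 * s0), 0, max(mu_new[3], 0.05 * s0))
    # shared emission SD: a per-state SD lets one state balloon into a
    # background component that swallows the other states' data
    ssq <- sum(vapply(1:3, function(s)
      sum(g_obs[, s] * (x[obs_idx] - mu[s])^2), numeric(1)))
    sdv <- rep(max(sqrt(ssq / sum(wsum)), 1e-4 * s0), 3)
    A <- xi_num / rowSums(xi_num)
    pi0 <- gam[1, ]
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }

  # state identity is anchored during EM: 1 downstream, 2 none, 3 upstream
  state_lab <- c(-1L, 0L, 1L)
  e <- dens()
  # Viterbi
  lA <- log(A); lp <- log(pi0 + 1e-300); le <- log(e + 1e-300)
  delta <- matrix(-Inf, n, 3); psi <- matrix(0L, n, 3)
  delta[1, ] <- lp + le[1, ]
  for (t in 2:n) {
    for (s in 1:3) {
      cand <- delta[t - 1, ] + lA[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- max(cand) + le[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states <- state_lab[path]      # -1 downstream, 0 none, +1 upstream

  # boundary: last non-none state was upstream (+1), next informative state
  # is downstream (-1); boundary placed at the first bin of the new domain
  informative <- which(states != 0L)
  boundaries <- integer(0)
  if (length(informative) >= 2L) {
    s <- states[informative]
    switch_idx <- which(s[-length(s)] == 1L & s[-1] == -1L)
    boundaries <- informative[switch_idx + 1L]
  }
  if (length(boundaries)) {
    starts <- c(1L, boundaries)
    ends <- c(boundaries - 1L, n)
    domains <- data.frame(start_bin = starts, end_bin = ends)
  } else {
    domains <- data.frame(start_bin = 1L, end_bin = n)
  }
  list(boundaries = boundaries, domains = domains, states = states)
}
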