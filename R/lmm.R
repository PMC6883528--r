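#' Random-intercept linear mixed model via profiled REML
#'
#' Fits `y = X beta + u[id] + e`, with one random intercept per individual,
#' by restricted maximum likelihood. The variance ratio
#' `lambda = sigma_u^2 / sigma_e^2` is profiled out and optimized on the
#' log scale; all other quantities have closed forms because the
#' random-intercept covariance inverts blockwise. Used throughout the QTL
#' machinery, where the same small model is fitted many thousands of times.
#'
#' The Wald test on a coefficient uses a t reference with
#' `df = N - n_individuals - 1`. If the REML fit fails, an ordinary least
#' squares fit is returned with `converged = FALSE`.
#'
#' @param y numeric response (one value per replicate-level observation).
#' @param x fixed-effect covariate (e.g. genotype dosage).
#' @param id individual identifier (coerced to factor).
#' @return list with `beta` (intercept, slope), `se`, `t`, `df`, `p`
#'   (for the slope), `sigma_u`, `sigma_e`, `lambda`, `converged`.
#' @export
fit_lmm <- function(y, x, id) {
  id <- factor(id)
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]; id <- droplevels(id[keep])
  n <- length(y)
  k <- nlevels(id)
  X <- cbind(1, x)
  p <- 2L
  if (n < p + 2L || stats::sd(x) == 0)
    stop("need non-constant covariate and > 3 observations")

  g <- as.integer(id)
  ni <- tabulate(g, k)

  # per-individual sums; V^-1 within group i is I - (lambda/(1+ni*lambda)) J
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- lam / (1 + ni * lam)         # per-group shrinkage
    Sy <- rowsum(y, g)[, 1]
    SX <- rowsum(X, g)
    XtVX <- crossprod(X) - crossprod(SX * sqrt(w[seq_len(k)]))
    XtVy <- crossprod(X, y) - colSums(SX * (Sy * w))
    beta <- solve(XtVX, XtVy)
    r <- y - X %*% beta
    Sr <- rowsum(as.vector(r), g)[, 1]
    rVr <- sum(r^2) - sum(w * Sr^2)
    s2 <- max(rVr / (n - p), 1e-300)   # guard exact fits
    ldV <- sum(log1p(ni * lam))
    ldX <- determinant(XtVX, logarithm = TRUE)$modulus
    nll <- 0.5 * ((n - p) * log(s2) + ldV + as.numeric(ldX))
    list(nll = nll, beta = beta, s2 = s2, XtVX = XtVX, lam = lam)
  }

  fit <- tryCatch({
    opt <- stats::optimize(function(l) prof(l)$nll, interval = c(-15, 15))
    pf <- prof(opt$minimum)
    # compare with the boundary lambda -> 0 (plain OLS)
    pf0 <- prof(-50)
    if (pf0$nll < pf$nll) pf <- pf0
    pf
  }, error = function(e) NULL)

  if (is.null(fit) || !all(is.finite(fit$beta))) {
    ols <- stats::lm.fit(X, y)
    s2 <- sum(ols$residuals^2) / (n - p)
    covb <- s2 * solve(crossprod(X))
    se <- sqrt(covb[2, 2])
    df <- n - k - 1
    tt <- ols$coefficients[2] / se
    return(list(beta = unname(ols$coefficients), se = se, t = unname(tt),
                df = df, p = 2 * stats::pt(-abs(tt), df),
                sigma_u = NA_real_, sigma_e = sqrt(s2),
                lambda = NA_real_, converged = FALSE))
  }
  covb <- fit$s2 * solve(fit$XtVX)
  se <- sqrt(covb[2, 2])
  df <- n - k - 1
  tt <- fit$beta[2] / se
  list(beta = as.vector(fit$beta), se = se, t = as.numeric(tt), df = df,
       p = as.numeric(2 * stats::pt(-abs(tt), df)),
       sigma_u = sqrt(fit$lam * fit$s2), sigma_e = sqrt(fit$s2),
       lambda = fit$lam, converged = TRUE)
}
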