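#' Covariate-based Poisson normalization of a raw contact matrix
#'
#' Removes systematic bias from effective fragment length, GC content and
#' mappability with a Poisson log-linear model: for off-diagonal cells
#' (i, j) the raw count is regressed on `log(eff_i * eff_j)` and
#' `log(gc_i * gc_j)` with `log(map_i * map_j)` as offset, and each cell is
#' replaced by observed / fitted. Bins with any covariate equal to zero are
#' unmappable and set to `NA` before fitting.
#'
#' @param cm a `contact_matrix` of raw integer counts.
#' @param cov data frame with per-bin columns `eff_len`, `gc`, `mappability`.
#' @return normalized `contact_matrix` with attribute `status` equal to
#'   `"ok"`, or `"unconverged"` if the GLM failed (matrix then returned
#'   unnormalized with a warning).
#' @export
hicnorm <- function(cm, cov) {
  v <- cm$values
  if (nrow(cov) != n_bins(cm))
    stop("covariate table must have one row per bin")
  ok <- !is.na(v)
  if (any(v[ok] != round(v[ok])))
    stop("hicnorm expects raw integer counts")
  bad <- which(cov$eff_len == 0 | cov$gc == 0 | cov$mappability == 0)
  cm <- mask_bins(cm, bad)
  v <- cm$values
  n <- n_bins(cm)

  ut <- which(upper.tri(v) & !is.na(v), arr.ind = TRUE)
  if (nrow(ut) < 10L) {
    warning("too few usable cells; matrix returned unnormalized")
    attr(cm, "status") <- "unconverged"
    return(cm)
  }
  i <- ut[, 1]; j <- ut[, 2]
  df <- data.frame(
    y = v[ut],
    leff = log(cov$eff_len[i] * cov$eff_len[j]),
    lgc = log(cov$gc[i] * cov$gc[j]),
    lmap = log(cov$mappability[i] * cov$mappability[j])
  )
  fit <- tryCatch(
    stats::glm(y ~ leff + lgc + offset(lmap), family = stats::poisson(),
               data = df),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || !fit$converged) {
    warning("Poisson normalization did not converge; ",
            "matrix returned unnormalized")
    attr(cm, "status") <- "unconverged"
    return(cm)
  }
  # predict for every cell (diagonal included) from the fitted coefficients
  co <- stats::coef(fit)
  co[is.na(co)] <- 0   # rank-deficient terms (e.g. constant covariate)
  eff <- log(cov$eff_len); gcv <- log(cov$gc); mp <- log(cov$mappability)
  lfit <- co[1] + co[2] * outer(eff, eff, "+") + co[3] * outer(gcv, gcv, "+") +
    outer(mp, mp, "+")
  out <- v / exp(lfit)
  cm$values <- out
  attr(cm, "status") <- "ok"
  cm
}

#' Quantile normalization across samples
#'
#' Replaces each sample's non-NA values by the mean of the order statistics
#' across samples at the same rank; ties receive the average of the tied
#' reference values. `NA` entries are excluded from ranking and restored as
#' `NA`. When samples have different numbers of non-NA entries, reference
#' quantiles are interpolated.
#'
#' @param xs list of numeric vectors, or of matrices with identical shape
#'   (values are normalized over all entries; for symmetric contact matrices
#'   pass `contact_matrix` objects).
#' @return list of the same shape, quantile normalized. With fewer than two
#'   samples the input is returned with a warning.
#' @export
quantile_normalize <- function(xs) {
  if (length(xs) < 2L) {
    warning("quantile normalization needs at least 2 samples; returning input")
    return(xs)
  }
  is_cm <- inherits(xs[[1]], "contact_matrix")
  vecs <- lapply(xs, function(x) {
    if (inherits(x, "contact_matrix")) as.vector(x$values) else as.vector(x)
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) stop("all samples must have the same shape")

  sorted <- lapply(vecs, function(v) sort(v[!is.na(v)]))
  m <- vapply(sorted, length, integer(1))
  if (any(m == 0L)) stop("a sample has no non-NA values")
  mref <- max(m)
  # reference distribution: mean across samples of order statistics, each
  # sample's sorted values interpolated onto a common grid of length mref
  grid <- if (mref == 1L) 0.5 else seq(0, 1, length.out = mref)
  ref <- rowMeans(vapply(sorted, function(s) {
    if (length(s) == 1L) rep(s, mref)
    else stats::approx(seq(0, 1, length.out = length(s)), s, xout = grid)$y
  }, numeric(mref)))

  out <- lapply(seq_along(vecs), function(k) {
    v <- vecs[[k]]
    obs <- which(!is.na(v))
    mk <- length(obs)
    refk <- if (mk == mref) ref
            else stats::approx(grid, ref, xout = seq(0, 1, length.out = mk))$y
    r <- rank(v[obs], ties.method = "average")
    # fractional (tied) ranks take the mean of the tied reference values
    v[obs] <- if (mk == 1L) refk else stats::approx(seq_len(mk), refk, xout = r)$y
    v
  })
  res <- lapply(seq_along(xs), function(k) {
    if (is_cm) {
      cm <- xs[[k]]
      cm$values <- matrix(out[[k]], n_bins(cm), n_bins(cm))
      cm
    } else if (is.matrix(xs[[k]])) {
      matrix(out[[k]], nrow(xs[[k]]), ncol(xs[[k]]))
    } else out[[k]]
  })
  names(res) <- names(xs)
  res
}

#' Observed-over-expected transform
#'
#' Divides each entry by the mean non-NA value at the same genomic distance
#' within the same matrix. Distances whose expected value is zero give `NA`.
#'
#' @param cm a normalized `contact_matrix`.
#' @return O/E `contact_matrix`; mean of non-NA entries at every distance is 1.
#' @export
oe_transform <- function(cm) {
  v <- cm$values
  n <- nrow(v)
  d <- abs(row(v) - col(v))
  expd <- vapply(0:(n - 1), function(k) {
    x <- v[d == k]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  e <- matrix(expd[d + 1L], n, n)
  out <- v / e
  out[!is.na(e) & e == 0] <- NA_real_
  cm$values <- out
  cm
}
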