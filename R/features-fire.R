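#' Per-bin short-range cis contact counts
#'
#' Sums, for every bin, the raw contacts to bins at anchor distances within
#' `[min_dist, max_dist]` (default 15-200 kb; contacts within `min_dist`,
#' including the diagonal, are excluded). These totals are the input to
#' [fire_scores()].
#'
#' @param cm a `contact_matrix` of raw counts.
#' @param min_dist,max_dist distance range in bp.
#' @return numeric per-bin count vector (NA for masked bins).
#' @export
fire_cis_counts <- function(cm, min_dist = 15e3, max_dist = 200e3) {
  bs <- cm$bin_size
  dmin <- max(1L, as.integer(ceiling(min_dist / bs)))
  dmax <- as.integer(floor(max_dist / bs))
  if (dmax < dmin) stop("distance range narrower than one bin")
  v <- cm$values
  n <- nrow(v)
  d <- abs(row(v) - col(v))
  v[d < dmin | d > dmax] <- NA
  out <- rowSums(v, na.rm = TRUE)
  out[rowSums(!is.na(v)) == 0] <- NA_real_
  masked <- na_bins(cm)
  out[masked] <- NA_real_
  out
}

#' FIRE scores and FIRE-bin calls
#'
#' Normalizes per-bin short-range cis contact totals with a per-sample
#' Poisson regression on effective fragment length and GC content with
#' mappability as offset (the cis analogue of [hicnorm()]), quantile
#' normalizes the observed/fitted ratios across samples, then transforms
#' with `log2(x + 1)` and converts to a per-sample z-score. A bin is called
#' a FIRE bin in a sample when its z-score exceeds the one-sided normal
#' critical value at `alpha` (default z > qnorm(0.95)).
#'
#' @param counts bins x samples matrix of short-range cis counts
#'   ([fire_cis_counts()] per sample).
#' @param cov per-bin covariates (`eff_len`, `gc`, `mappability`).
#' @param alpha one-sided significance level for FIRE calls.
#' @return list with `scores` (z-score matrix), `calls` (logical matrix),
#'   and `normalized` (post-quantile-normalization values).
#' @export
fire_scores <- function(counts, cov, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (nrow(cov) != nrow(counts))
    stop("covariate table must have one row per bin")
  bad <- cov$eff_len == 0 | cov$gc == 0 | cov$mappability == 0
  samples <- colnames(counts)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(counts)))
  norm <- matrix(NA_real_, nrow(counts), ncol(counts))
  for (k in seq_len(ncol(counts))) {
    y <- counts[, k]
    use <- !bad & !is.na(y)
    if (!any(use) || all(y[use] == 0))
      stop("sample '", samples[k], "' has all-zero cis counts")
    df <- data.frame(y = y[use], leff = log(cov$eff_len[use]),
                     lgc = log(cov$gc[use]),
                     lmap = log(cov$mappability[use]))
    fit <- stats::glm(y ~ leff + lgc + offset(lmap),
                      family = stats::poisson(), data = df)
    norm[use, k] <- y[use] / stats::fitted(fit)
  }
  qn <- quantile_normalize(lapply(seq_len(ncol(norm)), function(k) norm[, k]))
  qn <- do.call(cbind, qn)
  lg <- log2(qn + 1)
  z <- apply(lg, 2, function(x) (x - mean(x, na.rm = TRUE)) /
               stats::sd(x, na.rm = TRUE))
  calls <- !is.na(z) & z > stats::qnorm(1 - alpha)
  colnames(z) <- colnames(calls) <- colnames(qn) <- samples
  list(scores = z, calls = calls, normalized = qn)
}
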