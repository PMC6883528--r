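#' Directionality index
#'
#' For each bin, contacts to the upstream window (sum A) and the downstream
#' window (sum B) are compared with a signed two-cell chi-square statistic
#' under the null of equal contact: with E = (A + B) / 2,
#' DI = sign * ((A-E)^2/E + (B-E)^2/E) = sign * (A-B)^2/(A+B).
#' The sign is positive when A > B, i.e. positive DI means upstream bias.
#'
#' A bin gets `NA` when more than `max_na` bins of its window (bins falling
#' outside the chromosome included) are unusable, or when A + B = 0.
#'
#' @param cm a `contact_matrix` (quantile-normalized values or raw counts).
#' @param window one-sided window in bp; must be a multiple of the bin size.
#'   Default 2 Mb; the QTL search variant uses 200 kb.
#' @param max_na maximum tolerated NA bins in the two windows combined.
#' @return numeric per-bin DI vector.
#' @export
directionality_index <- function(cm, window = 2e6, max_na = 5L) {
  bs <- cm$bin_size
  if (window < bs || window %% bs != 0)
    stop("window must be a positive multiple of bin_size")
  w <- as.integer(window / bs)
  v <- cm$values
  n <- nrow(v)
  di <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    up <- (i - w):(i - 1)
    dn <- (i + 1):(i + w)
    n_out <- sum(up < 1) + sum(dn > n)
    up <- up[up >= 1]
    dn <- dn[dn <= n]
    a_vals <- v[i, up]
    b_vals <- v[i, dn]
    n_na <- n_out + sum(is.na(a_vals)) + sum(is.na(b_vals))
    if (n_na > max_na) next
    a <- sum(a_vals, na.rm = TRUE)
    b <- sum(b_vals, na.rm = TRUE)
    if (is.na(a + b) || a + b == 0) next
    di[i] <- sign(a - b) * (a - b)^2 / (a + b)
  }
  di
}

#' Chi-square threshold for strong directionality
#'
#' Critical value of the chi-squared distribution with 1 df used to flag
#' bins with strong directional bias, |DI| above the value corresponding to
#' a chi-squared test p-value of `p`.
#'
#' @param p tail probability (default 0.001).
#' @export
di_strong_threshold <- function(p = 0.001) {
  stats::qchisq(1 - p, df = 1)
}

#' Insulation score
#'
#' For each bin i with flanking windows U = upstream `w` bins and
#' D = downstream `w` bins, the score is the mean O/E value over U x D
#' cells (contacts crossing the bin) divided by the mean O/E value over
#' bin pairs inside U and inside D pooled (diagonal excluded), clipped at
#' 1. Scores range over [0, 1]: 0 is absolute insulation, 1 no insulation.
#'
#' `NA` when a window extends past the chromosome edge, or when more than
#' `max_na_frac` of the window's off-diagonal cells are NA.
#'
#' @param oe an O/E `contact_matrix` (see [oe_transform()]).
#' @param window one-sided window in bp; default 400 kb, QTL variant 200 kb.
#' @param max_na_frac maximum tolerated NA fraction in the window (0.5).
#' @param rescale `"clip"` (default) truncates the cross/within ratio at 1;
#'   `"minmax"` instead rescales the raw ratios to [0, 1] per chromosome.
#' @return numeric per-bin insulation vector in [0, 1] or NA.
#' @export
insulation_score <- function(oe, window = 400e3, max_na_frac = 0.5,
                             rescale = c("clip", "minmax")) {
  rescale <- match.arg(rescale)
  bs <- oe$bin_size
  if (window < bs || window %% bs != 0)
    stop("window must be a positive multiple of bin_size")
  w <- as.integer(window / bs)
  v <- oe$values
  n <- nrow(v)
  ins <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    u <- (i - w):(i - 1)
    d <- (i + 1):(i + w)
    win <- c(u, i, d)
    sub <- v[win, win]
    offd <- sub[upper.tri(sub)]
    if (mean(is.na(offd)) > max_na_frac) next
    cross <- v[u, d, drop = FALSE]
    wu <- v[u, u, drop = FALSE][upper.tri(diag(w))]
    wd <- v[d, d, drop = FALSE][upper.tri(diag(w))]
    cr <- mean(cross, na.rm = TRUE)
    wi <- mean(c(wu, wd), na.rm = TRUE)
    if (is.na(cr) || is.na(wi) || wi == 0) next
    ins[i] <- cr / wi
  }
  if (rescale == "clip") {
    pmin(ins, 1)
  } else {
    rng <- range(ins, na.rm = TRUE)
    if (diff(rng) == 0) ifelse(is.na(ins), NA_real_, 1) else
      (ins - rng[1]) / diff(rng)
  }
}
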