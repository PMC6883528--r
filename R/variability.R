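#' Testability mask for a 3D chromatin metric
#'
#' Applies the metric-specific inclusion rule (a bin must show appreciable
#' signal in at least one replicate) followed by the exclusion rules:
#' unreliable-covariate bins and their 200-kb neighborhood, configured
#' excluded regions (e.g. the MHC locus), and bins near large structural
#' variants with a metric-specific flank (FIRE 200 kb, INS 400 kb, DI 2 Mb,
#' PC1 direct overlap only).
#'
#' Inclusion rules: FIRE -- called FIRE in any replicate; DI -- |DI| above
#' the strong-bias chi-square threshold ([di_strong_threshold()]) in any
#' replicate; INS -- per-replicate z-scored INS below -1 in any replicate;
#' PC1 -- no metric filter.
#'
#' @param metric one of `"FIRE"`, `"DI"`, `"INS"`, `"PC1"`.
#' @param tracks bins x replicates matrix of scores (for FIRE, z-scores
#'   from [fire_scores()]; `fire_calls` may instead supply the call matrix).
#' @param cov per-bin covariates, or `NULL` to skip the covariate filter.
#' @param sv_bed data frame of structural variants (`start`, `end` in bp,
#'   0-based half-open) on this chromosome, or `NULL`.
#' @param exclude_bed data frame of excluded regions (`start`, `end`), or
#'   `NULL`.
#' @param bin_size bin width in bp.
#' @param fire_calls optional logical bins x replicates matrix of FIRE calls.
#' @param sv_min_len only SVs longer than this (bp) trigger flanked removal.
#' @return logical per-bin mask (`TRUE` = testable).
#' @export
select_testable_bins <- function(metric, tracks, cov = NULL, sv_bed = NULL,
                                 exclude_bed = NULL, bin_size = 40000L,
                                 fire_calls = NULL, sv_min_len = 10000L) {
  metric <- toupper(metric)
  if (!metric %in% c("FIRE", "DI", "INS", "PC1"))
    stop("unknown metric '", metric, "'")
  tracks <- as.matrix(tracks)
  n <- nrow(tracks)
  mask <- switch(metric,
    FIRE = if (!is.null(fire_calls)) rowSums(fire_calls, na.rm = TRUE) > 0
           else rowSums(tracks > stats::qnorm(0.95), na.rm = TRUE) > 0,
    DI = rowSums(abs(tracks) > di_strong_threshold(), na.rm = TRUE) > 0,
    INS = {
      z <- apply(tracks, 2, function(x)
        (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE))
      rowSums(z < -1, na.rm = TRUE) > 0
    },
    PC1 = rep(TRUE, n)
  )

  flank_bins <- function(flank_bp) as.integer(ceiling(flank_bp / bin_size))
  bins_overlapping <- function(bed) {
    if (is.null(bed) || nrow(bed) == 0) return(integer(0))
    unlist(lapply(seq_len(nrow(bed)), function(r) {
      lo <- floor(bed$start[r] / bin_size) + 1L
      hi <- ceiling(bed$end[r] / bin_size)
      lo:min(hi, n)
    }))
  }
  expand <- function(bins, fl) {
    if (!length(bins)) return(integer(0))
    out <- unique(unlist(lapply(bins, function(b) (b - fl):(b + fl))))
    out[out >= 1 & out <= n]
  }

  if (!is.null(cov)) {
    bad <- which(cov$eff_len == 0 | cov$gc == 0 | cov$mappability == 0)
    mask[expand(bad, flank_bins(200e3))] <- FALSE
  }
  mask[bins_overlapping(exclude_bed)] <- FALSE
  if (!is.null(sv_bed) && nrow(sv_bed)) {
    large <- sv_bed[sv_bed$end - sv_bed$start > sv_min_len, , drop = FALSE]
    sv_bins <- bins_overlapping(large)
    fl <- switch(metric, FIRE = flank_bins(200e3), INS = flank_bins(400e3),
                 DI = flank_bins(2e6), PC1 = 0L)
    mask[expand(sv_bins, fl)] <- FALSE
  }
  mask
}

# Closed-form moment matching of the scaled-F distribution of residual
# variances: estimates prior df d0 and prior variance s0^2 from
# e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2) by inverting the trigamma
# function with Newton steps. d0 clamped to (0, 1e6].
fit_f_dist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) return(list(d0 = 1e6, s0_2 = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  ev <- mean((e - ebar)^2) * length(e) / (length(e) - 1) -
    mean(trigamma(df / 2))
  if (!is.finite(ev) || ev <= 0)
    return(list(d0 = 1e6, s0_2 = exp(ebar)))
  # invert trigamma(d0/2) = ev
  y <- 0.5 + 1 / ev  # starting value (trigamma(x) ~ 1/x for large x)
  for (i in 1:50) {
    tri <- trigamma(y)
    delta <- tri * (1 - tri / ev) / psigamma(y, 2)
    y <- y + delta
    if (abs(delta) < 1e-10 * y) break
  }
  d0 <- min(2 * y, 1e6)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated F scan for inter-individual variability
#'
#' Per bin, fits the one-way fixed-effects model score ~ individual over
#' replicate-level tracks, shrinks the residual variances with an
#' empirical-Bayes estimator
#' `s2_tilde = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` whose
#' hyperparameters (d0, s0^2) come from closed-form moment matching on
#' log s_g^2, and tests the between-individual mean square against the
#' moderated variance with F on (k - 1, d0 + d_g) df. P-values are
#' BH-adjusted and adjacent significant bins are merged into variable
#' regions.
#'
#' @param scores bins x replicates matrix (rows may contain NA; bins with
#'   any NA or with zero residual df are excluded with a warning).
#' @param individual individual label per replicate column.
#' @param fdr FDR threshold for calling variable bins (default 0.1).
#' @param d0_override force the prior df (0 gives the ordinary one-way F;
#'   `Inf` shrinks every variance to s0^2); `NULL` estimates it.
#' @return list with `table` (per-bin statistics: `ms_between`, `s2`,
#'   `s2_tilde`, `f`, `p`, `q`, `df1`, `df2`), `d0`, `s0_2`, and `regions`
#'   (data frame `start_bin`, `end_bin` of merged significant runs).
#' @export
moderated_f_scan <- function(scores, individual, fdr = 0.1,
                             d0_override = NULL) {
  scores <- as.matrix(scores)
  individual <- factor(individual)
  if (ncol(scores) != length(individual))
    stop("one individual label per replicate column required")
  k <- nlevels(individual)
  if (k < 2L) stop("need at least 2 individuals")
  nrep <- table(individual)
  if (sum(nrep >= 2) < 2L) stop("need >= 2 replicates for >= 2 individuals")

  n_bin <- nrow(scores)
  usable <- rowSums(is.na(scores)) == 0
  g <- as.integer(individual)
  N <- ncol(scores)
  df1 <- k - 1L
  df2 <- N - k

  if (df2 < 1L) stop("zero residual df: need more replicates than individuals")
  if (any(!usable))
    warning(sum(!usable), " bin(s) with missing values excluded")

  gm <- rowMeans(scores)
  grp_sum <- scores %*% outer(g, seq_len(k), "==")  # bins x individuals
  grp_mean <- sweep(grp_sum, 2, as.numeric(nrep), "/")
  ssb <- rowSums(sweep((grp_mean - gm)^2, 2, as.numeric(nrep), "*"))
  sst <- rowSums((scores - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / df1
  s2 <- ssw / df2

  hp <- if (is.null(d0_override))
    fit_f_dist(s2[usable], rep(df2, sum(usable)))
  else list(d0 = d0_override, s0_2 = fit_f_dist(s2[usable],
                                rep(df2, sum(usable)))$s0_2)
  d0 <- hp$d0; s0_2 <- hp$s0_2
  s2t <- if (is.infinite(d0)) rep(s0_2, n_bin)
         else (d0 * s0_2 + df2 * s2) / (d0 + df2)
  fstat <- msb / s2t
  df2_mod <- if (is.infinite(d0)) Inf else d0 + df2
  p <- stats::pf(fstat, df1, df2_mod, lower.tail = FALSE)
  p[!usable] <- NA
  q <- rep(NA_real_, n_bin)
  q[usable] <- stats::p.adjust(p[usable], method = "BH")

  sig <- !is.na(q) & q < fdr
  regions <- merge_adjacent_bins(which(sig))
  list(table = data.frame(bin = seq_len(n_bin), ms_between = msb, s2 = s2,
                          s2_tilde = s2t, f = fstat, p = p, q = q,
                          df1 = df1, df2 = df2_mod),
       d0 = d0, s0_2 = s0_2, regions = regions)
}

#' Merge adjacent bin indices into maximal regions
#' @param bins sorted integer bin indices.
#' @return data frame `start_bin`, `end_bin`; idempotent by construction.
#' @export
merge_adjacent_bins <- function(bins) {
  bins <- sort(unique(as.integer(bins)))
  if (!length(bins))
    return(data.frame(start_bin = integer(0), end_bin = integer(0)))
  brk <- c(0, which(diff(bins) > 1), length(bins))
  data.frame(start_bin = bins[brk[-length(brk)] + 1],
             end_bin = bins[brk[-1]])
}

#' Bootstrap empirical FDR for the variable-bin scan
#'
#' Resamples replicate columns with replacement (keeping the original
#' individual design fixed, which breaks the replicate/individual pairing
#' and yields a background with no true individual effect), reruns the
#' moderated F scan, and reports empirical FDR = mean significant count
#' over bootstraps / observed significant count.
#'
#' @inheritParams moderated_f_scan
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list with `fdr` (NA when nothing is observed significant),
#'   `observed`, and `boot_counts`.
#' @export
empirical_fdr <- function(scores, individual, fdr = 0.1, n_boot = 1000L,
                          seed = 1L) {
  scores <- as.matrix(scores)
  obs <- sum(moderated_f_scan(scores, individual, fdr = fdr)$table$q < fdr,
             na.rm = TRUE)
  set.seed(seed)
  counts <- vapply(seq_len(n_boot), function(b) {
    cols <- sample(ncol(scores), replace = TRUE)
    sum(moderated_f_scan(scores[, cols, drop = FALSE], individual,
                         fdr = fdr)$table$q < fdr, na.rm = TRUE)
  }, numeric(1))
  list(fdr = if (obs == 0) NA_real_ else mean(counts) / obs,
       observed = obs, boot_counts = counts)
}

# Storey-style covariate-weighted BH: tests are split into equal-count
# strata of the covariate, per-stratum weights proportional to the
# estimated non-null proportion (1 - pi0 at lambda = 0.5) and normalized
# to mean 1, then BH applied to p / w. One stratum reduces exactly to BH.
# Strata need enough tests for a stable pi0 estimate, so the stratum count
# shrinks (down to plain BH) when tests are few.
ihw_adjust <- function(p, covariate, n_strata = 10L, lambda = 0.5,
                       min_stratum = 50L) {
  n <- length(p)
  n_strata <- min(n_strata, n %/% min_stratum)
  if (n_strata <= 1L || length(unique(covariate)) < n_strata) {
    strata <- rep(1L, n)
  } else {
    qs <- unique(stats::quantile(covariate, seq(0, 1, length.out =
                                                  n_strata + 1)))
    strata <- as.integer(cut(covariate, qs, include.lowest = TRUE))
  }
  w <- rep(1, n)
  if (length(unique(strata)) > 1L) {
    for (s in unique(strata)) {
      sel <- strata == s
      pi0 <- min(1, mean(p[sel] > lambda, na.rm = TRUE) / (1 - lambda))
      w[sel] <- 1 - pi0
    }
    if (all(w == 0)) w[] <- 1
    w <- w / mean(w)
  }
  pw <- ifelse(w > 0, pmin(p / w, 1), 1)
  stats::p.adjust(pw, method = "BH")
}

#' Inter-individual variability of contact matrix cells
#'
#' For each batch-corrected matrix cell within `max_distance`, tests the
#' individual effect with a one-way F test on replicate-level values,
#' adjusts p-values with a covariate-weighted BH procedure using anchor
#' distance as the informative covariate, and decomposes each cell's
#' variance into between-individual (biological) and within-individual
#' (technical) components with moment estimators from the one-way
#' random-effects model.
#'
#' @param cells cells x samples matrix of corrected values.
#' @param individual individual label per sample column.
#' @param distance_bp anchor distance per cell (bp).
#' @param max_distance only cells closer than this are tested (28 Mb).
#' @param fdr significance threshold on the adjusted q (default 0.1).
#' @param n_strata distance strata for the weighting (default 10).
#' @return data frame with per-cell `f`, `p`, `q`, `var_between`,
#'   `var_within`, `tested`, `significant`.
#' @export
cell_variability_scan <- function(cells, individual, distance_bp,
                                  max_distance = 28e6, fdr = 0.1,
                                  n_strata = 10L) {
  cells <- as.matrix(cells)
  individual <- factor(individual)
  k <- nlevels(individual)
  g <- as.integer(individual)
  nrep <- as.numeric(table(individual))
  N <- ncol(cells)
  df1 <- k - 1L; df2 <- N - k
  if (df2 < 1L) stop("need replicates to estimate within-individual variance")

  tested <- distance_bp < max_distance
  gm <- rowMeans(cells)
  grp_mean <- sweep(cells %*% outer(g, seq_len(k), "=="), 2, nrep, "/")
  ssb <- rowSums(sweep((grp_mean - gm)^2, 2, nrep, "*"))
  sst <- rowSums((cells - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / df1
  msw <- ssw / df2
  fstat <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, NA))
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  # balanced-design moment decomposition (coincides with the ML/REML
  # random-intercept decomposition for equal replicate counts)
  n0 <- (N - sum(nrep^2) / N) / df1
  var_between <- pmax((msb - msw) / n0, 0)

  q <- rep(NA_real_, nrow(cells))
  q[tested] <- ihw_adjust(p[tested], distance_bp[tested],
                          n_strata = n_strata)
  data.frame(cell = seq_len(nrow(cells)), distance_bp = distance_bp,
             f = fstat, p = ifelse(tested, p, NA), q = q,
             var_between = var_between, var_within = msw,
             tested = tested,
             significant = !is.na(q) & q < fdr)
}

#' Correlation of variable regions with external per-individual tracks
#'
#' Collapses runs of consecutive variable bins to the bin with the
#' strongest external signal, computes the Spearman correlation across
#' individuals between the 3D feature and the external track at each
#' retained bin, and assesses the median correlation against a null built
#' by permuting the individual labels of the external data.
#'
#' @param regions data frame `start_bin`, `end_bin` (e.g. from
#'   [moderated_f_scan()]).
#' @param feature bins x individuals matrix of the 3D metric.
#' @param external bins x individuals matrix of the external signal.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `table` (bin, rho), `median_rho`, `perm_medians`,
#'   and two-sided `p` (fraction of permutations with |median| >=
#'   |observed|, permutation itself included).
#' @export
correlate_with_tracks <- function(regions, feature, external,
                                  n_perm = 10000L, seed = 1L) {
  feature <- as.matrix(feature); external <- as.matrix(external)
  if (ncol(feature) < 4L)
    stop("rank correlation needs at least 4 individuals")
  if (!nrow(regions)) stop("no regions supplied")
  bins <- vapply(seq_len(nrow(regions)), function(r) {
    span <- regions$start_bin[r]:regions$end_bin[r]
    strength <- rowMeans(abs(external[span, , drop = FALSE]), na.rm = TRUE)
    span[which.max(strength)]
  }, integer(1))

  rho_at <- function(ext) {
    vapply(bins, function(b)
      suppressWarnings(stats::cor(feature[b, ], ext[b, ],
                                  method = "spearman")), numeric(1))
  }
  rho <- rho_at(external)
  obs <- stats::median(rho, na.rm = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::median(rho_at(external[, sample(ncol(external)), drop = FALSE]),
                  na.rm = TRUE)
  }, numeric(1))
  p <- (sum(abs(perm) >= abs(obs)) + 1) / (n_perm + 1)
  list(table = data.frame(bin = bins, rho = rho), median_rho = obs,
       perm_medians = perm, p = p)
}

#' Within- vs between-individual replicate reproducibility
#'
#' Computes Pearson correlations for all pairs of replicate tracks, labels
#' each pair as within-individual or between-individual, and compares the
#' two groups with a two-sided rank-sum test.
#'
#' @param tracks bins x replicates matrix of scores.
#' @param individual individual label per replicate column.
#' @return list with `pairs` (data frame `sample_a`, `sample_b`, `r`,
#'   `group`), group medians, and rank-sum `p` (NA when a group has zero
#'   variance or either group is empty).
#' @export
reproducibility_summary <- function(tracks, individual) {
  tracks <- as.matrix(tracks)
  individual <- as.character(individual)
  S <- ncol(tracks)
  cmb <- utils::combn(S, 2)
  r <- apply(cmb, 2, function(ij)
    suppressWarnings(stats::cor(tracks[, ij[1]], tracks[, ij[2]],
                                use = "complete.obs")))
  grp <- ifelse(individual[cmb[1, ]] == individual[cmb[2, ]],
                "within", "between")
  pairs <- data.frame(sample_a = cmb[1, ], sample_b = cmb[2, ], r = r,
                      group = grp)
  wi <- r[grp == "within"]; be <- r[grp == "between"]
  p <- if (!length(wi) || !length(be) ||
           (stats::sd(c(wi, be)) == 0 || is.na(stats::sd(c(wi, be)))))
    NA_real_
  else suppressWarnings(stats::wilcox.test(wi, be, exact = FALSE,
                                           correct = TRUE)$p.value)
  list(pairs = pairs,
       median_within = stats::median(wi),
       median_between = stats::median(be), p = p)
}

#' Per-distance replicate correlations for contact matrices
#'
#' For each anchor distance, computes Pearson correlations between all
#' sample pairs over the cells at that distance and labels pairs as
#' within- or between-individual.
#'
#' @param cms list of `contact_matrix` objects.
#' @param individual individual label per matrix.
#' @param max_band largest distance (bins) to report.
#' @return data frame `band`, `sample_a`, `sample_b`, `r`, `group`.
#' @export
matrix_reproducibility <- function(cms, individual, max_band = 25L) {
  bands <- extract_bands(cms, max_band = max_band)
  individual <- as.character(individual)
  out <- lapply(seq_along(bands), function(b) {
    bm <- bands[[b]]
    cmb <- utils::combn(nrow(bm), 2)
    r <- apply(cmb, 2, function(ij)
      suppressWarnings(stats::cor(bm[ij[1], ], bm[ij[2], ])))
    data.frame(band = b, sample_a = cmb[1, ], sample_b = cmb[2, ], r = r,
               group = ifelse(individual[cmb[1, ]] == individual[cmb[2, ]],
                              "within", "between"))
  })
  do.call(rbind, out)
}
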