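#' Nominal fraction of QTL SNPs in another association scan
#'
#' Computes the fraction of QTL SNPs reaching nominal significance
#' (p < `alpha`) in another study's raw test results, and compares it to
#' the non-QTL tested SNPs with a 2x2 chi-square test. For contact scans
#' where one SNP is tested against several matrix cells, reduce the scan
#' to each SNP's minimum p first (see [reduce_min_p()]).
#'
#' @param qtl_snps character vector of QTL SNP ids (set Y).
#' @param scan data frame `snp_id`, `p`: raw association results for
#'   phenotype X (the tested universe).
#' @param alpha nominal significance level (default 0.05).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `fraction` (NA when no QTL SNP was tested, with
#'   counts reported), `background_fraction`, `chisq_p`, `n_qtl_tested`,
#'   `n_background`.
#' @export
nominal_fraction <- function(qtl_snps, scan, alpha = 0.05,
                             correct = FALSE) {
  qtl_snps <- unique(qtl_snps)
  in_y <- scan$snp_id %in% qtl_snps
  nqt <- sum(in_y)
  if (!nqt)
    return(list(fraction = NA_real_, background_fraction = NA_real_,
                chisq_p = NA_real_, n_qtl_tested = 0L,
                n_background = sum(!in_y)))
  hit_y <- sum(scan$p[in_y] < alpha)
  hit_bg <- sum(scan$p[!in_y] < alpha)
  n_bg <- sum(!in_y)
  frac <- hit_y / nqt
  chisq_p <- if (n_bg == 0) NA_real_ else {
    tab <- matrix(c(hit_y, nqt - hit_y, hit_bg, n_bg - hit_bg), 2,
                  byrow = TRUE)
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  }
  list(fraction = frac, background_fraction = if (n_bg) hit_bg / n_bg
       else NA_real_, chisq_p = chisq_p, n_qtl_tested = nqt,
       n_background = n_bg)
}

#' Reduce a cell-level scan to one p-value per SNP
#'
#' Keeps each SNP's most significant (minimum) p-value, so SNPs tested
#' against many matrix cells are not over-weighted.
#'
#' @param scan data frame `snp_id`, `p` with possibly repeated SNPs.
#' @return data frame with one row per SNP.
#' @export
reduce_min_p <- function(scan) {
  ord <- order(scan$snp_id, scan$p)
  scan <- scan[ord, , drop = FALSE]
  scan[!duplicated(scan$snp_id), , drop = FALSE]
}

#' Permutation null for the nominal fraction
#'
#' Repeatedly draws `size` SNPs from the tested universe (without
#' replacement within a draw; draws independent across permutations),
#' computes the nominal fraction of each draw, and reports the bootstrap
#' p-value: the fraction of permutations whose nominal fraction is at
#' least the observed one.
#'
#' @param observed_fraction the observed nominal fraction of the QTL set.
#' @param scan data frame `snp_id`, `p` (the tested universe).
#' @param size number of SNPs per draw (the QTL set size).
#' @param alpha nominal significance level.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `boot_p`, `perm_fractions`.
#' @export
bootstrap_null <- function(observed_fraction, scan, size, alpha = 0.05,
                           n_perm = 10000L, seed = 1L) {
  if (size > nrow(scan)) stop("size exceeds the tested universe")
  set.seed(seed)
  hits <- scan$p < alpha
  n <- nrow(scan)
  perm <- vapply(seq_len(n_perm), function(i)
    mean(hits[sample.int(n, size)]), numeric(1))
  list(boot_p = mean(perm >= observed_fraction), perm_fractions = perm)
}

#' Enrichment of QTL SNPs among nominal hits of an external scan
#'
#' Extends the QTL set with its perfect-LD partners (and applies the same
#' extension to the tested-SNP control universe), computes
#' enrichment = QTL nominal fraction / tested-universe nominal fraction,
#' with chi-square and permutation significance.
#'
#' @param qtl_snps character vector of QTL SNP ids.
#' @param scan data frame `snp_id`, `p` (external summary statistics).
#' @param ld data frame `snp_id`, `partner_id` giving perfect-LD partners
#'   within the same bin, or `NULL` for no extension.
#' @param alpha nominal significance level.
#' @param n_perm permutations for the bootstrap p (default 10000).
#' @param seed RNG seed.
#' @return list with `enrichment` (NA when the universe fraction is 0),
#'   `fraction`, `background_fraction`, `chisq_p`, `boot_p`.
#' @export
external_enrichment <- function(qtl_snps, scan, ld = NULL, alpha = 0.05,
                                n_perm = 10000L, seed = 1L) {
  extend <- function(ids) {
    if (is.null(ld)) return(unique(ids))
    unique(c(ids, ld$partner_id[ld$snp_id %in% ids]))
  }
  y <- extend(qtl_snps)
  nf <- nominal_fraction(y, scan, alpha = alpha)
  universe_frac <- mean(scan$p < alpha)
  enr <- if (universe_frac > 0 && !is.na(nf$fraction))
    nf$fraction / universe_frac else NA_real_
  boot <- if (!is.na(nf$fraction))
    bootstrap_null(nf$fraction, scan, size = nf$n_qtl_tested,
                   alpha = alpha, n_perm = n_perm, seed = seed)$boot_p
  else NA_real_
  list(enrichment = enr, fraction = nf$fraction,
       background_fraction = nf$background_fraction,
       chisq_p = nf$chisq_p, boot_p = boot)
}
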