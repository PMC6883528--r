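#' A/B compartment score (PC1) from an O/E matrix
#'
#' The O/E matrix is transformed to a Pearson correlation matrix over bins
#' (NA bins dropped and restored afterwards) and the eigenvectors of the
#' covariance of that correlation matrix are computed. The first eigenvector
#' usually captures A/B compartmentalization, but on some chromosomes it
#' instead tracks features such as chromosome arms; the chromosome is
#' therefore accepted only when eigenvector 1 has the highest absolute
#' correlation with gene density among the first three. Gene density is
#' used only for this check and to orient the sign (positive PC1 = higher
#' gene density, compartment A) -- never in the eigen computation itself.
#'
#' @param oe an O/E `contact_matrix`.
#' @param gene_density per-bin gene-density vector.
#' @return list with `status` (`"ok"` or `"rejected"`), `pc1` (per-bin
#'   score, NA where rejected or masked), `density_cor` (absolute
#'   correlations of the top three eigenvectors with gene density) and
#'   `eigenvectors` (top three, NA-restored).
#' @export
compartment_pc1 <- function(oe, gene_density) {
  n <- n_bins(oe)
  if (length(gene_density) != n)
    stop("gene_density must have one value per bin")
  keep <- setdiff(seq_len(n), na_bins(oe))
  reject <- function() list(status = "rejected", pc1 = rep(NA_real_, n),
                            density_cor = rep(NA_real_, 3),
                            eigenvectors = matrix(NA_real_, n, 3))
  if (length(keep) < 4L) return(reject())
  sub <- oe$values[keep, keep]
  if (any(is.na(sub))) {
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
  } else {
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0)) return(reject())
    cc <- stats::cor(sub)
  }
  ev <- tryCatch(eigen(stats::cov(cc), symmetric = TRUE),
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev$values[1:3]))) return(reject())
  vecs <- matrix(NA_real_, n, 3)
  vecs[keep, ] <- ev$vectors[, 1:3]
  dc <- abs(apply(vecs, 2, function(x)
    suppressWarnings(stats::cor(x, gene_density, use = "complete.obs"))))
  dc[is.na(dc)] <- 0
  if (which.max(dc) != 1L)
    return(modifyList(reject(), list(density_cor = dc, eigenvectors = vecs)))
  pc1 <- vecs[, 1]
  s <- stats::cor(pc1, gene_density, use = "complete.obs")
  if (!is.na(s) && s < 0) pc1 <- -pc1
  list(status = "ok", pc1 = pc1, density_cor = dc, eigenvectors = vecs)
}
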