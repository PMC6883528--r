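#' Extract distance bands across samples
#'
#' Converts each sample's contact matrix to log2 counts-per-million
#' (CPM computed per chromosome per sample over the upper triangle
#' including the diagonal, log offset 0.5) and slices the cells at each
#' fixed anchor distance ("band") into a samples-by-cells matrix.
#'
#' @param cms list of `contact_matrix` objects with identical dimensions.
#' @param max_band largest band (anchor distance in bins) to extract;
#'   default all bands.
#' @param log_offset offset added inside the log (default 0.5).
#' @return list of bands; band `b` is a samples x (n - b) matrix of
#'   log2(CPM + offset) values for cells (i, i + b).
#' @export
extract_bands <- function(cms, max_band = NULL, log_offset = 0.5) {
  ns <- vapply(cms, n_bins, integer(1))
  if (length(unique(ns)) != 1L) stop("matrices must share dimensions")
  n <- ns[1]
  if (is.null(max_band)) max_band <- n - 1L
  max_band <- min(max_band, n - 1L)
  logs <- lapply(cms, function(cm) {
    v <- cm$values
    tot <- sum(v[upper.tri(v, diag = TRUE)], na.rm = TRUE)
    log2(1e6 * v / tot + log_offset)
  })
  bands <- lapply(seq_len(max_band), function(b) {
    idx <- cbind(seq_len(n - b), seq_len(n - b) + b)
    do.call(rbind, lapply(logs, function(m) m[idx]))
  })
  names(bands) <- paste0("band", seq_len(max_band))
  bands
}

# Location/scale batch adjustment with parametric empirical-Bayes shrinkage
# (normal prior on per-cell batch means, inverse-gamma on per-cell batch
# variances), applied to a cells x samples matrix. Both mean and variance
# are corrected. Cells with zero pooled variance pass through unchanged.
combat_adjust <- function(mat, batch, eb_tol = 1e-4, eb_max_iter = 100L) {
  batch <- factor(batch)
  levs <- levels(batch)
  if (length(levs) < 2L) return(mat)
  nb <- table(batch)
  G <- nrow(mat); S <- ncol(mat)

  # cell-wise grand mean and within-batch pooled variance (standardization)
  batch_means <- vapply(levs, function(b)
    rowMeans(mat[, batch == b, drop = FALSE]), numeric(G))
  grand <- as.vector(batch_means %*% (as.numeric(nb) / S))
  resid <- mat - batch_means[, as.integer(batch), drop = FALSE]
  pooled_var <- rowSums(resid^2) / S
  usable <- pooled_var > 0
  if (!any(usable)) return(mat)
  z <- (mat[usable, , drop = FALSE] - grand[usable]) /
    sqrt(pooled_var[usable])

  out_z <- z
  for (b in levs) {
    sel <- batch == b
    nbk <- sum(sel)
    zb <- z[, sel, drop = FALSE]
    ghat <- rowMeans(zb)
    dhat <- rowSums((zb - ghat)^2) / max(1, nbk - 1)
    dhat[dhat == 0] <- min(dhat[dhat > 0], 1)

    # hyperpriors by method of moments
    gbar <- mean(ghat); t2 <- stats::var(ghat)
    if (!is.finite(t2) || t2 == 0) t2 <- 1e-8
    m <- mean(dhat); v <- stats::var(dhat)
    if (!is.finite(v) || v == 0) v <- 1e-8
    a_pr <- (2 * v + m^2) / v
    b_pr <- (m * v + m^3) / v

    gstar <- ghat; dstar <- dhat
    for (it in seq_len(eb_max_iter)) {
      g_new <- (t2 * nbk * ghat + dstar * gbar) / (t2 * nbk + dstar)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * ss + b_pr) / (nbk / 2 + a_pr - 1)
      change <- max(abs(g_new - gstar) / pmax(abs(gstar), 1e-8),
                    abs(d_new - dstar) / pmax(dstar, 1e-8))
      gstar <- g_new; dstar <- d_new
      if (change < eb_tol) break
    }
    out_z[, sel] <- (zb - gstar) / sqrt(dstar)
  }
  res <- mat
  res[usable, ] <- out_z * sqrt(pooled_var[usable]) + grand[usable]
  res
}

#' Bandwise normalization and batch correction
#'
#' For each anchor-distance band of the chromosome, the samples' log-CPM
#' values are quantile normalized across samples and known batch effects
#' are regressed out with a parametric empirical-Bayes location/scale
#' adjustment (both mean and variance corrected), conditioning on genomic
#' distance throughout. The 8 most distal bands, where the number of cells
#' is too small to estimate batch parameters, are set to 0, as is the
#' diagonal. With a single batch the adjustment step is the identity and
#' the output is the per-band quantile-normalized input.
#'
#' @param cms list of `contact_matrix` objects (raw counts), one per
#'   replicate.
#' @param batch batch label per sample.
#' @param n_distal number of most-distal bands set to zero (default 8).
#' @param drop_singleton_batches if `TRUE`, samples in batches with a
#'   single member are dropped (with a warning) instead of raising.
#' @return list of corrected `contact_matrix` objects (log2-CPM scale,
#'   float values), in input order; dropped samples are absent.
#' @export
bnbc_correct <- function(cms, batch, n_distal = 8L,
                         drop_singleton_batches = FALSE) {
  if (length(batch) != length(cms))
    stop("one batch label per sample required")
  batch <- factor(batch)
  singletons <- names(which(table(batch) == 1L))
  if (length(singletons)) {
    if (!drop_singleton_batches)
      stop("batch '", singletons[1],
           "' has a single sample; batch parameters cannot be estimated ",
           "(set drop_singleton_batches = TRUE to drop such samples)")
    keep <- !(as.character(batch) %in% singletons)
    warning("dropping ", sum(!keep), " sample(s) in singleton batches")
    cms <- cms[keep]
    batch <- droplevels(batch[keep])
  }
  n <- n_bins(cms[[1]])
  total_bands <- n - 1L
  n_correct <- max(0L, total_bands - n_distal)
  bands <- extract_bands(cms)

  out_vals <- lapply(cms, function(cm) matrix(0, n, n))
  for (b in seq_len(n_correct)) {
    bm <- bands[[b]]                       # samples x cells
    qn <- quantile_normalize(lapply(seq_len(nrow(bm)), function(k) bm[k, ]))
    qn <- do.call(rbind, qn)
    adj <- t(combat_adjust(t(qn), batch))  # combat works cells x samples
    idx <- cbind(seq_len(n - b), seq_len(n - b) + b)
    for (k in seq_along(cms)) {
      out_vals[[k]][idx] <- adj[k, ]
      out_vals[[k]][idx[, 2:1]] <- adj[k, ]
    }
  }
  out <- lapply(seq_along(cms), function(k) {
    cm <- cms[[k]]
    cm$values <- out_vals[[k]]
    cm
  })
  names(out) <- names(cms)
  out
}
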