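#' Select testable SNPs for QTL mapping
#'
#' Keeps biallelic SNPs, drops restriction-site polymorphism positions,
#' requires minor allele frequency >= `maf_min` among the discovery
#' individuals with both alleles carried by at least `min_carriers`
#' individuals, assigns each SNP to its 40-kb bin, restricts to testable
#' bins, and collapses perfect-LD groups within each bin (identical dosage
#' vectors up to a global allele swap, computed on discovery individuals)
#' to the SNP with the smallest genomic position.
#'
#' @param genotypes data frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, then one dosage column per individual (0/1/2, missing
#'   -1).
#' @param testable_bins logical per-bin mask (`NULL` keeps all bins).
#' @param discovery_ids individual column names forming the discovery set.
#' @param hindiii_excl positions to exclude (restriction-site
#'   polymorphisms).
#' @param bin_size bin width in bp.
#' @param maf_min MAF threshold (default 0.05).
#' @param min_carriers minimum individuals carrying each allele.
#' @return data frame of surviving SNPs with `bin`, `maf`, `ld_group`,
#'   `is_tag`.
#' @export
select_test_snps <- function(genotypes, testable_bins = NULL, discovery_ids,
                             hindiii_excl = integer(0), bin_size = 40000L,
                             maf_min = 0.05, min_carriers = 2L) {
  if (!length(discovery_ids)) stop("empty discovery set")
  if (!all(discovery_ids %in% colnames(genotypes)))
    stop("discovery individuals missing from genotype table")
  g <- genotypes
  biallelic <- nchar(g$ref) == 1 & nchar(g$alt) == 1 &
    !grepl(",", g$alt, fixed = TRUE) & g$ref != g$alt
  g <- g[biallelic & !(g$pos %in% hindiii_excl), , drop = FALSE]
  if (!nrow(g)) return(cbind(g, bin = integer(0), maf = numeric(0),
                             ld_group = integer(0), is_tag = logical(0)))
  dos <- as.matrix(g[, discovery_ids, drop = FALSE])
  dos[dos < 0] <- NA
  n_obs <- rowSums(!is.na(dos))
  af <- rowSums(dos, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(af, 1 - af)
  carriers_alt <- rowSums(dos > 0, na.rm = TRUE)
  carriers_ref <- rowSums(dos < 2, na.rm = TRUE)
  keep <- n_obs > 0 & maf >= maf_min & carriers_alt >= min_carriers &
    carriers_ref >= min_carriers
  g <- g[keep, , drop = FALSE]
  dos <- dos[keep, , drop = FALSE]
  maf <- maf[keep]
  g$bin <- floor((g$pos - 1) / bin_size) + 1L
  if (!is.null(testable_bins)) {
    ok <- g$bin <= length(testable_bins) & testable_bins[g$bin]
    g <- g[ok, , drop = FALSE]; dos <- dos[ok, , drop = FALSE]
    maf <- maf[ok]
  }
  g$maf <- maf
  if (!nrow(g)) {
    g$ld_group <- integer(0); g$is_tag <- logical(0)
    return(g)
  }
  # perfect-LD signature: dosage vector canonicalized under allele swap
  sig <- apply(dos, 1, function(d) {
    a <- paste(d, collapse = ",")
    b <- paste(2 - d, collapse = ",")
    min(a, b)
  })
  key <- paste(g$chrom, g$bin, sig, sep = "|")
  g$ld_group <- as.integer(factor(key, levels = unique(key)))
  ord <- order(g$ld_group, g$pos)
  first <- !duplicated(g$ld_group[ord])
  g$is_tag <- FALSE
  g$is_tag[ord[first]] <- TRUE
  rownames(g) <- NULL
  g
}

#' Replicate-level LMM association scan for bin phenotypes
#'
#' For every testable bin and every tag SNP assigned to that bin, fits the
#' random-intercept model replicate score ~ dosage + (1 | individual) by
#' REML ([fit_lmm()]) and reports the Wald test on the genotype
#' coefficient. SNPs with constant dosage among the scanned individuals
#' are skipped with a reason.
#'
#' @param scores bins x samples matrix of replicate-level phenotype values
#'   (use the 200-kb-window DI/INS variants for those phenotypes).
#' @param snps output of [select_test_snps()] (only `is_tag` rows are
#'   scanned).
#' @param individual individual label per sample column (must match
#'   genotype column names).
#' @return list with `table` (data frame `snp_id`, `bin`, `pos`, `beta`,
#'   `se`, `p`, `converged`), `skipped` (data frame `snp_id`, `reason`)
#'   and `inflation` (`median_p`, `lambda`).
#' @export
lmm_scan <- function(scores, snps, individual) {
  scores <- as.matrix(scores)
  individual <- as.character(individual)
  tags <- snps[snps$is_tag, , drop = FALSE]
  rows <- vector("list", nrow(tags))
  skipped <- list()
  for (r in seq_len(nrow(tags))) {
    b <- tags$bin[r]
    if (b > nrow(scores)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(snp_id = tags$snp_id[r], reason = "bin out of range")
      next
    }
    dose <- as.numeric(tags[r, individual])
    dose[dose < 0] <- NA
    y <- scores[b, ]
    ok <- !is.na(dose) & !is.na(y)
    if (sum(ok) < 4L || stats::sd(dose[ok]) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(snp_id = tags$snp_id[r], reason = "constant genotype")
      next
    }
    fit <- fit_lmm(y[ok], dose[ok], individual[ok])
    rows[[r]] <- data.frame(snp_id = tags$snp_id[r], bin = b,
                            pos = tags$pos[r], beta = fit$beta[2],
                            se = fit$se, p = fit$p,
                            converged = fit$converged)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab))
    tab <- data.frame(snp_id = character(0), bin = integer(0),
                      pos = integer(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), converged = logical(0))
  lambda <- if (nrow(tab))
    stats::median(stats::qchisq(1 - tab$p, 1)) / stats::qchisq(0.5, 1)
  else NA_real_
  list(table = tab,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(snp_id = character(0), reason = character(0)),
       inflation = list(median_p = if (nrow(tab)) stats::median(tab$p)
                        else NA_real_, lambda = lambda))
}

#' Classify DI bins by dominant bias direction
#'
#' A bin is "upstream" when the DI value with the largest absolute value
#' among the discovery individuals is positive, otherwise "downstream".
#'
#' @param di_scores bins x individuals matrix of DI values.
#' @return character per-bin vector (`"upstream"`/`"downstream"`, NA when
#'   all values missing).
#' @export
classify_di_bins <- function(di_scores) {
  di_scores <- as.matrix(di_scores)
  apply(di_scores, 1, function(x) {
    if (all(is.na(x))) return(NA_character_)
    if (x[which.max(abs(x))] > 0) "upstream" else "downstream"
  })
}

#' Call QTLs from a scan with FDR control and a best-SNP rule
#'
#' Applies BH FDR within the phenotype (for DI, the upstream- and
#' downstream-bias bin classes are adjusted separately to avoid a
#' Simpson's-paradox artifact) and keeps, per bin, only the most
#' significantly associated SNP (ties broken by smallest position).
#'
#' @param scan output of [lmm_scan()].
#' @param phenotype label stored in the output (`"FIRE"`, `"DI"`, `"INS"`,
#'   `"CONTACT"`).
#' @param fdr FDR threshold (default 0.2).
#' @param di_class per-bin class vector from [classify_di_bins()] (DI
#'   only).
#' @return data frame of QTL records (`phenotype`, `bin`, `snp_id`, `pos`,
#'   `beta`, `p`, `q`, `direction`), one row per significant bin.
#' @export
call_qtls <- function(scan, phenotype = "FIRE", fdr = 0.2, di_class = NULL) {
  tab <- scan$table
  if (!nrow(tab))
    return(data.frame(phenotype = character(0), bin = integer(0),
                      snp_id = character(0), pos = integer(0),
                      beta = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0)))
  if (!is.null(di_class)) {
    cls <- di_class[tab$bin]
    tab$q <- NA_real_
    for (cl in unique(stats::na.omit(cls))) {
      sel <- !is.na(cls) & cls == cl
      tab$q[sel] <- stats::p.adjust(tab$p[sel], method = "BH")
    }
  } else {
    tab$q <- stats::p.adjust(tab$p, method = "BH")
  }
  sig <- tab[!is.na(tab$q) & tab$q < fdr, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(phenotype = character(0), bin = integer(0),
                      snp_id = character(0), pos = integer(0),
                      beta = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0)))
  sig <- sig[order(sig$bin, sig$p, sig$pos), , drop = FALSE]
  best <- sig[!duplicated(sig$bin), , drop = FALSE]
  data.frame(phenotype = phenotype, bin = best$bin, snp_id = best$snp_id,
             pos = best$pos, beta = best$beta, p = best$p, q = best$q,
             direction = ifelse(best$beta > 0, "increase", "decrease"),
             row.names = NULL)
}

#' Contact-QTL scan over variable matrix cells
#'
#' Tests each variable matrix cell against the tag SNPs falling in either
#' of its anchor bins with the same random-intercept LMM as [lmm_scan()],
#' adjusts p-values with the covariate-weighted BH procedure using anchor
#' distance as covariate, and reports the most significant SNP per
#' significant cell; when the best SNP has perfect-LD partners among the
#' SNPs of the two anchor bins, the leftmost member of the group is
#' reported.
#'
#' @param cells cells x samples matrix of batch-corrected contact values.
#' @param cell_anchors data frame `anchor_i`, `anchor_j` (bin indices) per
#'   cell row.
#' @param snps output of [select_test_snps()] (tags and LD partners).
#' @param individual individual label per sample column.
#' @param fdr FDR threshold (default 0.2).
#' @param bin_size bin width in bp (for the distance covariate).
#' @return list with `tests` (all fitted tests) and `qtls` (one row per
#'   significant cell).
#' @export
cqtl_scan <- function(cells, cell_anchors, snps, individual, fdr = 0.2,
                      bin_size = 40000L) {
  cells <- as.matrix(cells)
  individual <- as.character(individual)
  tags <- snps[snps$is_tag, , drop = FALSE]
  rows <- list()
  for (ci in seq_len(nrow(cell_anchors))) {
    anchors <- c(cell_anchors$anchor_i[ci], cell_anchors$anchor_j[ci])
    cand <- tags[tags$bin %in% anchors, , drop = FALSE]
    if (!nrow(cand)) next
    y <- cells[ci, ]
    for (r in seq_len(nrow(cand))) {
      dose <- as.numeric(cand[r, individual])
      dose[dose < 0] <- NA
      ok <- !is.na(dose) & !is.na(y)
      if (sum(ok) < 4L || stats::sd(dose[ok]) == 0) next
      fit <- fit_lmm(y[ok], dose[ok], individual[ok])
      rows[[length(rows) + 1]] <-
        data.frame(cell = ci, anchor_i = anchors[1], anchor_j = anchors[2],
                   snp_id = cand$snp_id[r], pos = cand$pos[r],
                   ld_group = cand$ld_group[r],
                   distance_bp = (anchors[2] - anchors[1]) * bin_size,
                   beta = fit$beta[2], p = fit$p)
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), anchor_i = integer(0),
               anchor_j = integer(0), snp_id = character(0),
               pos = integer(0), ld_group = integer(0),
               distance_bp = numeric(0), beta = numeric(0), p = numeric(0))
  if (nrow(tests)) {
    tests$q <- ihw_adjust(tests$p, tests$distance_bp)
  } else tests$q <- numeric(0)
  sig <- tests[!is.na(tests$q) & tests$q < fdr, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$cell, sig$p, sig$pos), , drop = FALSE]
    qtls <- sig[!duplicated(sig$cell), , drop = FALSE]
    # report the leftmost member of the best SNP's perfect-LD group among
    # the SNPs of the two anchor bins
    for (r in seq_len(nrow(qtls))) {
      grp <- snps[snps$ld_group == qtls$ld_group[r] &
                    snps$bin %in% c(qtls$anchor_i[r], qtls$anchor_j[r]), ,
                  drop = FALSE]
      if (nrow(grp)) {
        left <- grp[which.min(grp$pos), ]
        qtls$snp_id[r] <- left$snp_id
        qtls$pos[r] <- left$pos
      }
    }
  } else qtls <- sig
  rownames(qtls) <- NULL
  list(tests = tests, qtls = qtls)
}

#' Validate QTLs in held-out individuals
#'
#' Pools the held-out replicate-level phenotype values across QTLs with
#' dosages oriented so that the discovery direction of effect is positive
#' (dose of the phenotype-increasing allele), regresses the per-QTL
#' centered phenotype on oriented dosage, and assesses the pooled slope
#' against a null built by repeatedly sampling the same number of random
#' (bin, SNP) pairs from the testable universe.
#'
#' @param qtls QTL records from [call_qtls()].
#' @param scores bins x held-out samples phenotype matrix.
#' @param genotypes genotype table containing the held-out individuals
#'   (missing dosages coded -1 are dropped).
#' @param individual individual label per held-out sample column.
#' @param universe data frame `bin`, `snp_id`, `pos` plus dosage columns:
#'   the testable (bin, SNP) universe to sample the null from.
#' @param n_perm number of null draws (default 1000).
#' @param seed RNG seed.
#' @return list with `slope`, `lm_p`, `perm_slopes`, `boot_p` (fraction of
#'   null slopes >= observed).
#' @export
validate_qtls <- function(qtls, scores, genotypes, individual,
                          universe = NULL, n_perm = 1000L, seed = 1L) {
  if (!nrow(qtls)) stop("nothing to validate")
  scores <- as.matrix(scores)
  individual <- as.character(individual)
  if (!any(individual %in% colnames(genotypes)))
    stop("no held-out individuals with genotypes")

  pooled_slope <- function(bins, snp_rows, orient) {
    ys <- c(); gs <- c()
    for (r in seq_along(bins)) {
      b <- bins[r]
      if (b > nrow(scores)) next
      dose <- as.numeric(snp_rows[r, individual])
      dose[dose < 0] <- NA
      if (orient[r] < 0) dose <- 2 - dose
      y <- scores[b, ]
      ok <- !is.na(dose) & !is.na(y)
      if (sum(ok) < 2L) next
      ys <- c(ys, y[ok] - mean(y[ok]))
      gs <- c(gs, dose[ok])
    }
    if (length(ys) < 3L || stats::sd(gs) == 0) return(c(NA_real_, NA_real_))
    fit <- stats::lm(ys ~ gs)
    c(stats::coef(fit)[2], summary(fit)$coefficients[2, 4])
  }

  qrows <- genotypes[match(qtls$snp_id, genotypes$snp_id), , drop = FALSE]
  obs <- pooled_slope(qtls$bin, qrows, sign(qtls$beta))
  if (is.na(obs[1])) stop("validation regression degenerate")

  boot_p <- NA_real_; perm_slopes <- numeric(0)
  if (!is.null(universe) && nrow(universe)) {
    set.seed(seed)
    ubins <- unique(universe$bin)
    perm_slopes <- vapply(seq_len(n_perm), function(i) {
      bsel <- sample(ubins, min(nrow(qtls), length(ubins)))
      rows <- vapply(bsel, function(b) {
        cand <- which(universe$bin == b)
        cand[sample.int(length(cand), 1)]
      }, integer(1))
      pooled_slope(universe$bin[rows],
                   universe[rows, , drop = FALSE],
                   rep(1, length(rows)))[1]
    }, numeric(1))
    boot_p <- (sum(perm_slopes >= obs[1], na.rm = TRUE) + 1) /
      (sum(!is.na(perm_slopes)) + 1)
  }
  list(slope = unname(obs[1]), lm_p = unname(obs[2]),
       perm_slopes = perm_slopes, boot_p = boot_p)
}

#' Aggregate genotype-contrast submatrices around targets
#'
#' For each target matrix cell, extracts the (2*flank+1)^2 submatrix
#' centred on it from every individual's matrix, averages submatrices per
#' recoded genotype (doses of the phenotype-increasing allele), forms the
#' contrasts (2 - 1) and (1 - 0), and averages the contrasts across
#' targets. Submatrices containing missing values, and targets too close
#' to the chromosome edge, are discarded and counted.
#'
#' @param targets data frame `anchor_i`, `anchor_j` (use `anchor_j =
#'   anchor_i` for bin-level targets such as loops).
#' @param mats list of matrices (or `contact_matrix` objects), one per
#'   individual.
#' @param dosages targets x individuals matrix of recoded doses (0/1/2;
#'   NA dropped).
#' @param flank_bins flank size in bins (15 for loops, 25 for C-QTLs).
#' @return list with `d21`, `d10` (mean contrast maps), `n_used`,
#'   `n_skipped`.
#' @export
aggregate_submatrices <- function(targets, mats, dosages, flank_bins = 25L) {
  mats <- lapply(mats, function(m)
    if (inherits(m, "contact_matrix")) m$values else as.matrix(m))
  n <- nrow(mats[[1]])
  w <- 2L * flank_bins + 1L
  acc21 <- matrix(0, w, w); acc10 <- matrix(0, w, w)
  n21 <- 0L; n10 <- 0L; skipped <- 0L
  for (t in seq_len(nrow(targets))) {
    i <- targets$anchor_i[t]; j <- targets$anchor_j[t]
    ri <- (i - flank_bins):(i + flank_bins)
    rj <- (j - flank_bins):(j + flank_bins)
    if (min(ri) < 1 || min(rj) < 1 || max(ri) > n || max(rj) > n) {
      skipped <- skipped + 1L
      next
    }
    means <- vector("list", 3)
    counts <- integer(3)
    for (gg in 0:2) {
      idx <- which(!is.na(dosages[t, ]) & dosages[t, ] == gg)
      if (!length(idx)) next
      subs <- lapply(idx, function(k) mats[[k]][ri, rj])
      subs <- subs[!vapply(subs, anyNA, logical(1))]
      if (!length(subs)) next
      means[[gg + 1]] <- Reduce(`+`, subs) / length(subs)
      counts[gg + 1] <- length(subs)
    }
    if (counts[3] > 0 && counts[2] > 0) {
      acc21 <- acc21 + (means[[3]] - means[[2]]); n21 <- n21 + 1L
    }
    if (counts[2] > 0 && counts[1] > 0) {
      acc10 <- acc10 + (means[[2]] - means[[1]]); n10 <- n10 + 1L
    }
  }
  list(d21 = if (n21) acc21 / n21 else matrix(NA_real_, w, w),
       d10 = if (n10) acc10 / n10 else matrix(NA_real_, w, w),
       n_used = c(d21 = n21, d10 = n10), n_skipped = skipped)
}

#' Monte Carlo power of the replicate-level LMM QTL test
#'
#' Simulates, for each run, per-subject dosages as the sum of two
#' binomial(1, maf) allele draws, replicate-level responses
#' `mean + beta * dose + subject intercept + residual` with 2 replicates
#' per subject, fits the same random-intercept LMM used by the QTL scans,
#' and reports power as the fraction of runs rejecting the null of no
#' genotype effect at `alpha`.
#'
#' @param maf minor allele frequency.
#' @param beta genotype effect size per alt dose.
#' @param subject_sd between-subject (random intercept) SD.
#' @param residual_sd residual SD.
#' @param n_subjects number of subjects (default 11).
#' @param n_replicates replicates per subject (default 2).
#' @param n_sim simulation runs (default 1000).
#' @param alpha nominal test level (default 0.05).
#' @param cell_mean baseline mean (contact phenotype; default 0).
#' @param seed RNG seed.
#' @return list with `power`, `n_tested` (runs with non-constant
#'   genotype), `rejections`.
#' @export
power_simulation <- function(maf, beta, subject_sd, residual_sd,
                             n_subjects = 11L, n_replicates = 2L,
                             n_sim = 1000L, alpha = 0.05, cell_mean = 0,
                             seed = 1L) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (subject_sd < 0 || residual_sd < 0) stop("SDs must be non-negative")
  set.seed(seed)
  rej <- 0L; tested <- 0L
  id <- rep(seq_len(n_subjects), each = n_replicates)
  for (s in seq_len(n_sim)) {
    dose <- stats::rbinom(n_subjects, 1, maf) +
      stats::rbinom(n_subjects, 1, maf)
    if (stats::sd(dose) == 0) next
    u <- stats::rnorm(n_subjects, 0, subject_sd)
    y <- cell_mean + beta * dose[id] + u[id] +
      stats::rnorm(length(id), 0, residual_sd)
    fit <- fit_lmm(y, dose[id], id)
    tested <- tested + 1L
    if (fit$p < alpha) rej <- rej + 1L
  }
  list(power = if (tested) rej / tested else NA_real_, n_tested = tested,
       rejections = rej)
}
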