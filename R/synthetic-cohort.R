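#' Configuration for a synthetic Hi-C cohort
#'
#' Describes a multi-individual, multi-replicate cohort on one synthetic
#' chromosome. The defaults mirror a 20-individual, two-replicate
#' lymphoblastoid design on a 16-Mb chromosome of 400 40-kb bins, with the
#' two replicates of every individual processed in two different batches.
#'
#' All randomness downstream flows from `seed` through fixed per-component
#' offsets (genotypes +1, covariates +2, replicate matrices +3 onward,
#' epigenome tracks +101, haplotype reads +102).
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_replicates replicates per individual (default 2).
#' @param chrom_length chromosome length in bp (default 16 Mb).
#' @param bin_size bin width in bp (default 40 kb).
#' @param depth_per_replicate expected intra-chromosomal read-pair count
#'   per replicate.
#' @param decay_exponent power-law slope of contact decay with distance.
#' @param maf_range allele-frequency sampling range, within (0, 0.5].
#' @param batch_assignment batch label per replicate index (default:
#'   replicate r is batch `paste0("batch", r)`).
#' @param overdispersion extra-Poisson noise: counts are Poisson with a
#'   gamma-multiplied mean of shape `1/overdispersion` when > 0 (default 0,
#'   plain Poisson).
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20L, n_replicates = 2L,
                       chrom_length = 16e6, bin_size = 40000L,
                       depth_per_replicate = 5e5, decay_exponent = 1.0,
                       maf_range = c(0.05, 0.5), batch_assignment = NULL,
                       overdispersion = 0, seed = 1L) {
  if (n_individuals < 2) stop("need at least 2 individuals")
  if (bin_size <= 0) stop("bin_size must be positive")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range bounds must lie in (0, 0.5]")
  if (is.null(batch_assignment))
    batch_assignment <- paste0("batch", seq_len(n_replicates))
  if (length(batch_assignment) != n_replicates)
    stop("every replicate needs a batch label")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_replicates = as.integer(n_replicates),
    chrom_length = chrom_length, bin_size = as.integer(bin_size),
    n_bins = bin_count(chrom_length, bin_size),
    depth_per_replicate = depth_per_replicate,
    decay_exponent = decay_exponent, maf_range = maf_range,
    batch_assignment = batch_assignment,
    overdispersion = overdispersion, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Planted ground truth for a synthetic cohort
#'
#' Encodes the structures the pipeline is meant to recover: a per-bin
#' compartment vector in [-1, 1], TAD boundaries, FIRE bins with boost
#' factors, focal loops, genotype effects on local contact features, and
#' per-band batch distortions. Defaults give alternating compartment
#' blocks of `comp_block` bins, TAD boundaries every `tad_size` bins, 5%
#' FIRE bins with boost 2, and a handful of loops of strength 3.
#'
#' @param config a `sim_config`.
#' @param comp_block compartment block length in bins.
#' @param comp_strength coupling of the compartment checkerboard
#'   (log-scale coefficient).
#' @param tad_size TAD length in bins.
#' @param tad_boost within-TAD contact enrichment factor (> 1).
#' @param fire_fraction fraction of bins planted as FIREs.
#' @param fire_boost per-end contact boost at FIRE bins (short range).
#' @param loops data frame `anchor_i`, `anchor_j`, `strength` (anchor_i <
#'   anchor_j), or `NULL` for an automatic sparse set.
#' @param qtl_effects list of entries `list(snp_id =, target =, phenotype
#'   = "FIRE"|"DI"|"INS"|"CONTACT"|"LOOP", beta =)`; `target` is a bin
#'   index (or `c(i, j)` for CONTACT/LOOP). Betas act per alt dose on the
#'   log contact scale.
#' @param batch_band_sd SD of per-band log-scale shifts for every batch
#'   after the first (first batch is the reference, shift 0).
#' @param batch_shift fixed per-band shift added to non-reference batches
#'   on top of the random part (default 0).
#' @return list of class `truth_set`.
#' @export
truth_set <- function(config, comp_block = 50L, comp_strength = 0.3,
                      tad_size = 20L, tad_boost = 2, fire_fraction = 0.05,
                      fire_boost = 2, loops = NULL, qtl_effects = list(),
                      batch_band_sd = 0.3, batch_shift = 0) {
  n <- config$n_bins
  comp <- rep(rep(c(1, -1), length.out = ceiling(n / comp_block)),
              each = comp_block)[seq_len(n)]
  tad_bounds <- seq(tad_size + 1L, n, by = tad_size)
  set.seed(config$seed)
  fire_bins <- sort(sample(n, max(1, round(fire_fraction * n))))
  if (is.null(loops)) {
    starts <- tad_bounds[seq(1, length(tad_bounds) - 1, by = 4)]
    loops <- data.frame(anchor_i = starts, anchor_j = starts + tad_size,
                        strength = 3)
    loops <- loops[loops$anchor_j <= n, , drop = FALSE]
  }
  if (any(loops$anchor_i >= loops$anchor_j))
    stop("loop anchors must satisfy anchor_i < anchor_j")
  batches <- unique(config$batch_assignment)
  batch_effects <- matrix(0, n - 1L, length(batches),
                          dimnames = list(NULL, batches))
  if (length(batches) > 1) {
    for (b in seq_along(batches)[-1])
      batch_effects[, b] <- stats::rnorm(n - 1L, batch_shift, batch_band_sd)
  }
  structure(list(compartment_vector = comp, tad_boundaries = tad_bounds,
                 fire_bins = fire_bins, fire_boost = fire_boost,
                 tad_boost = tad_boost, comp_strength = comp_strength,
                 loops = loops, qtl_effects = qtl_effects,
                 batch_effects = batch_effects),
            class = "truth_set")
}

#' Simulate genotype dosages
#'
#' Each SNP gets an allele frequency drawn uniformly from the config's
#' `maf_range`; each individual's dosage is the sum of two independent
#' Bernoulli(freq) allele draws. Positions are strictly increasing along
#' the synthetic chromosome.
#'
#' @param config a `sim_config`.
#' @param n_snps number of SNPs (>= 1).
#' @param maf fixed allele frequency for all SNPs (overrides `maf_range`;
#'   0 is allowed for degenerate checks).
#' @return data frame `snp_id`, `chrom`, `pos`, `ref`, `alt`, one dosage
#'   column per individual (`ind01`, ...).
#' @export
simulate_genotypes <- function(config, n_snps, maf = NULL) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (!is.null(maf) && (any(maf < 0) || any(maf > 0.5)))
    stop("fixed maf must lie in [0, 0.5]")
  set.seed(config$seed + 1L)
  n_ind <- config$n_individuals
  pos <- sort(sample(config$chrom_length, n_snps))
  freq <- if (is.null(maf))
    stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
  else rep_len(maf, n_snps)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  dos <- vapply(seq_len(n_ind), function(i)
    stats::rbinom(n_snps, 1, freq) + stats::rbinom(n_snps, 1, freq),
    numeric(n_snps))
  dos <- matrix(dos, nrow = n_snps)
  colnames(dos) <- sprintf("ind%02d", seq_len(n_ind))
  cbind(data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
                   chrom = "chrS", pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE),
        as.data.frame(dos))
}

#' Simulate per-bin covariates
#'
#' Effective fragment length, GC content and mappability drawn from
#' positive distributions, with a configurable fraction of bins set to
#' zero mappability to exercise the unreliable-bin filters.
#'
#' @param n_bins number of bins.
#' @param zero_fraction fraction of bins made unreliable (default 0).
#' @param seed RNG seed.
#' @return data frame `bin`, `eff_len`, `gc`, `mappability`.
#' @export
simulate_bin_covariates <- function(n_bins, zero_fraction = 0, seed = 2L) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  set.seed(seed)
  cov <- data.frame(
    bin = seq_len(n_bins),
    eff_len = stats::rgamma(n_bins, shape = 20, scale = 1000),
    gc = stats::runif(n_bins, 0.33, 0.62),
    mappability = stats::runif(n_bins, 0.7, 1)
  )
  nz <- round(zero_fraction * n_bins)
  if (nz > 0) {
    zero <- sample(n_bins, nz)
    cov$mappability[zero] <- 0
  }
  cov
}

# expected-intensity matrix for one individual (log scale, no batch term)
cohort_log_lambda <- function(config, truth, dosage_fun) {
  n <- config$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ll <- -config$decay_exponent * log(d + 1)
  ll <- ll + truth$comp_strength * outer(truth$compartment_vector,
                                         truth$compartment_vector)
  # TAD enrichment: both bins inside the same domain
  dom <- findInterval(seq_len(n), c(1, truth$tad_boundaries))
  same <- outer(dom, dom, "==")
  ll <- ll + log(truth$tad_boost) * same
  # FIRE boost acts at short range (the 15-200 kb scoring window)
  bs <- config$bin_size
  short <- d >= max(1, ceiling(15e3 / bs)) & d <= floor(200e3 / bs)
  fire <- seq_len(n) %in% truth$fire_bins
  fmat <- outer(fire, fire, "|") & short
  ll <- ll + log(truth$fire_boost) * fmat
  for (l in seq_len(nrow(truth$loops))) {
    i <- truth$loops$anchor_i[l]; j <- truth$loops$anchor_j[l]
    ll[i, j] <- ll[i, j] + log(truth$loops$strength[l])
    ll[j, i] <- ll[i, j]
  }
  # genotype effects
  for (q in truth$qtl_effects) {
    dose <- dosage_fun(q$snp_id)
    if (is.na(dose) || dose == 0) next
    eff <- q$beta * dose
    ph <- toupper(q$phenotype)
    if (ph %in% c("CONTACT", "LOOP")) {
      i <- q$target[1]; j <- q$target[2]
      ll[i, j] <- ll[i, j] + eff
      ll[j, i] <- ll[i, j]
    } else if (ph == "FIRE") {
      b <- q$target[1]
      sel <- short[b, ]
      ll[b, sel] <- ll[b, sel] + eff
      ll[sel, b] <- t(ll[b, sel])
    } else if (ph == "INS") {
      b <- q$target[1]
      w <- max(1, floor(200e3 / bs))
      up <- max(1, b - w):(b - 1); dn <- (b + 1):min(n, b + w)
      if (b > 1 && b < n) {
        ll[up, dn] <- ll[up, dn] + eff
        ll[dn, up] <- t(ll[up, dn])
      }
    } else if (ph == "DI") {
      b <- q$target[1]
      w <- max(1, floor(200e3 / bs))
      up <- (b - w):(b - 1); up <- up[up >= 1]
      dn <- (b + 1):(b + w); dn <- dn[dn <= n]
      ll[b, up] <- ll[b, up] + eff / 2
      ll[up, b] <- ll[b, up]
      ll[b, dn] <- ll[b, dn] - eff / 2
      ll[dn, b] <- ll[b, dn]
    } else stop("unknown QTL phenotype '", q$phenotype, "'")
  }
  ll
}

#' Simulate the cohort's contact matrices
#'
#' Builds, for each individual, an expected-intensity matrix combining
#' power-law distance decay, a compartment checkerboard, within-TAD
#' enrichment, short-range FIRE boosts, focal loops and any planted
#' genotype effects; adds the replicate's per-band batch distortion; and
#' draws symmetric Poisson counts scaled to the configured depth.
#' Replicates of one individual share all genotype-driven structure and
#' differ only by sampling noise and batch.
#'
#' @param config a `sim_config`.
#' @param truth a `truth_set` consistent with the config.
#' @param genotypes genotype table from [simulate_genotypes()] (may be
#'   `NULL` when no QTL effects are planted).
#' @return named list of `contact_matrix` objects, one per replicate
#'   (`ind01_rep1`, ...), with attributes `individual`, `replicate`,
#'   `batch`.
#' @export
simulate_cohort_matrices <- function(config, truth, genotypes = NULL) {
  if (length(truth$compartment_vector) != config$n_bins)
    stop("truth set does not match config bin count")
  n <- config$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  out <- list()
  for (i in seq_len(config$n_individuals)) {
    ind <- sprintf("ind%02d", i)
    dosage_fun <- function(snp) {
      if (is.null(genotypes)) return(0)
      r <- match(snp, genotypes$snp_id)
      if (is.na(r)) stop("QTL SNP '", snp, "' absent from genotype table")
      genotypes[[ind]][r]
    }
    ll <- cohort_log_lambda(config, truth, dosage_fun)
    for (r in seq_len(config$n_replicates)) {
      batch <- config$batch_assignment[r]
      shift <- truth$batch_effects[, batch]
      llr <- ll
      band_shift <- c(0, shift)[pmin(d, n - 1L) + 1L]
      llr <- llr + matrix(band_shift, n, n)
      lam <- exp(llr)
      lam <- lam * (2 * config$depth_per_replicate /
                      (sum(lam) + sum(diag(lam))))
      set.seed(config$seed + 2L + (i - 1L) * config$n_replicates + r)
      if (config$overdispersion > 0) {
        sh <- 1 / config$overdispersion
        mult <- matrix(stats::rgamma(n * n, shape = sh, rate = sh), n, n)
        mult[lower.tri(mult)] <- t(mult)[lower.tri(mult)]
        lam <- lam * mult
      }
      up <- which(upper.tri(lam, diag = TRUE))
      cnt <- matrix(0, n, n)
      cnt[up] <- stats::rpois(length(up), lam[up])
      cnt <- cnt + t(cnt) - diag(diag(cnt))
      cm <- contact_matrix(cnt, chrom = "chrS", bin_size = config$bin_size)
      attr(cm, "individual") <- ind
      attr(cm, "replicate") <- r
      attr(cm, "batch") <- batch
      out[[paste0(ind, "_rep", r)]] <- cm
    }
  }
  out
}

#' Sample sheet for a simulated cohort
#' @param config a `sim_config`.
#' @return data frame `sample`, `individual`, `replicate`, `batch`.
#' @export
cohort_sample_sheet <- function(config) {
  ind <- sprintf("ind%02d", rep(seq_len(config$n_individuals),
                                each = config$n_replicates))
  rep_i <- rep(seq_len(config$n_replicates), config$n_individuals)
  data.frame(sample = paste0(ind, "_rep", rep_i), individual = ind,
             replicate = rep_i,
             batch = config$batch_assignment[rep_i])
}

#' Simulate external epigenome tracks correlated with a 3D feature
#'
#' At the designated bins, the synthetic track has expected
#' across-individual correlation `rho` with the given feature (a scaled
#' copy plus independent noise under a bivariate-normal construction);
#' everywhere else the track is independent noise.
#'
#' @param feature bins x individuals matrix of the 3D metric.
#' @param target_bins bins where the correlation is planted.
#' @param rho target correlation in [-1, 1].
#' @param seed RNG seed.
#' @return bins x individuals matrix.
#' @export
simulate_epigenome_tracks <- function(feature, target_bins, rho,
                                      seed = 101L) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  feature <- as.matrix(feature)
  set.seed(seed)
  out <- matrix(stats::rnorm(length(feature)), nrow(feature),
                ncol(feature))
  for (b in target_bins) {
    f <- feature[b, ]
    if (stats::sd(f) == 0) next
    z <- (f - mean(f)) / stats::sd(f)
    out[b, ] <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(f))
  }
  colnames(out) <- colnames(feature)
  out
}

#' Simulate haplotype-resolved loop reads for heterozygotes
#'
#' Per (loop, heterozygous individual): the total loop-read count equals
#' `depth` and the strong-haplotype count is Binomial(depth, imbalance).
#'
#' @param n_loops number of loops.
#' @param het_individuals character vector of heterozygous individuals.
#' @param imbalance probability a loop read falls on the strong haplotype
#'   (in [0, 1]).
#' @param depth total loop reads per (loop, individual); scalar or vector
#'   recycled over loops.
#' @param seed RNG seed.
#' @return data frame `loop`, `individual`, `s_count`, `w_count`.
#' @export
simulate_loop_haplotype_reads <- function(n_loops, het_individuals,
                                          imbalance, depth, seed = 102L) {
  if (imbalance < 0 || imbalance > 1) stop("imbalance must lie in [0, 1]")
  set.seed(seed)
  depth <- rep_len(depth, n_loops)
  grid <- expand.grid(loop = seq_len(n_loops),
                      individual = het_individuals,
                      stringsAsFactors = FALSE)
  tot <- depth[grid$loop]
  s <- stats::rbinom(nrow(grid), tot, imbalance)
  data.frame(grid, s_count = s, w_count = tot - s)
}

#' Write a simulated cohort to plain-text files
#'
#' Sparse triplet TSV per replicate, genotype TSV, covariate TSV, sample
#' sheet TSV and a JSON-like truth summary.
#'
#' @param cms list of matrices from [simulate_cohort_matrices()].
#' @param genotypes genotype table (or `NULL`).
#' @param cov covariate table (or `NULL`).
#' @param config the `sim_config`.
#' @param outdir output directory (created if needed).
#' @export
write_cohort <- function(cms, genotypes, cov, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cms))
    write_triplets(cms[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  if (!is.null(genotypes))
    utils::write.table(genotypes, file.path(outdir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cov))
    utils::write.table(cov, file.path(outdir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort_sample_sheet(config),
                     file.path(outdir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
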