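# --- testable-bin selection -------------------------------------------------

test_that("metric filters and flanked exclusions behave as specified", {
  n <- 400
  tracks <- matrix(0, n, 4)
  # DI: no replicate passes the strong-bias threshold at bin 5
  tracks[5, ] <- 10.0
  tracks[6, 1] <- 11.0   # just above 10.82757
  mask <- select_testable_bins("DI", tracks)
  expect_false(mask[5])
  expect_true(mask[6])

  # SV flank arithmetic: 50-kb SV at bin 10 removes [5, 16] for FIRE
  sv <- data.frame(start = 9 * 40000, end = 9 * 40000 + 50000)
  fire_z <- matrix(3, n, 4)   # every bin called somewhere
  m2 <- select_testable_bins("FIRE", fire_z, sv_bed = sv)
  covered <- 10:11            # bins overlapping the SV (360-410 kb)
  flank <- 5L                 # 200 kb / 40 kb
  removed <- (min(covered) - flank):(max(covered) + flank)
  expect_true(all(!m2[removed]))
  expect_true(m2[min(removed) - 1])
  expect_true(m2[max(removed) + 1])

  # all filters off -> everything testable for PC1
  expect_true(all(select_testable_bins("PC1", tracks)))
  expect_error(select_testable_bins("XYZ", tracks), "unknown metric")
})

test_that("unreliable covariate bins are removed with a 200-kb margin", {
  n <- 100
  cov <- flat_covariates(n)
  cov$mappability[50] <- 0
  mask <- select_testable_bins("PC1", matrix(0, n, 2), cov = cov)
  expect_true(all(!mask[45:55]))
  expect_true(mask[44] && mask[56])
})

test_that("INS testability uses per-sample z-scores below -1", {
  n <- 200
  tracks <- matrix(0.5, n, 4)
  tracks[7, ] <- 0.05   # strongly insulated in every replicate
  mask <- select_testable_bins("INS", tracks)
  expect_true(mask[7])
  expect_false(mask[8])
})

# --- moderated F ------------------------------------------------------------

test_that("d0 forced to 0 reproduces the ordinary one-way ANOVA F", {
  set.seed(82)
  scores <- matrix(rnorm(100 * 22), 100)
  ind <- factor(rep(1:11, each = 2))
  mf <- moderated_f_scan(scores, ind, d0_override = 0)
  for (b in sample(100, 25)) {
    a <- anova(stats::lm(scores[b, ] ~ ind))
    expect_equal(mf$table$f[b], a$`F value`[1], tolerance = 1e-8)
    expect_equal(mf$table$p[b], a$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("d0 forced to infinity ranks bins by between-individual MS", {
  set.seed(83)
  scores <- matrix(rnorm(50 * 22, sd = rep(runif(50, 0.5, 2), 22)), 50)
  ind <- factor(rep(1:11, each = 2))
  mf <- moderated_f_scan(scores, ind, d0_override = Inf)
  expect_true(all(mf$table$s2_tilde == mf$s0_2))
  expect_equal(order(mf$table$f), order(mf$table$ms_between))
})

test_that("estimated hyperparameters match the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(84)
  v <- exp(rnorm(300, 0, 1))
  scores <- t(sapply(v, function(s) rnorm(22, 0, sqrt(s))))
  ind <- factor(rep(1:11, each = 2))
  mf <- moderated_f_scan(scores, ind)
  fit <- limma::eBayes(limma::lmFit(scores, stats::model.matrix(~ind)))
  expect_equal(mf$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mf$s0_2, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mf$table$s2_tilde, fit$s2.post, tolerance = 1e-8)
})

test_that("shrunk variance lies between the bin and prior variances", {
  set.seed(85)
  scores <- matrix(rnorm(200 * 8), 200)
  ind <- factor(rep(1:4, each = 2))
  mf <- moderated_f_scan(scores, ind)
  lo <- pmin(mf$table$s2, mf$s0_2); hi <- pmax(mf$table$s2, mf$s0_2)
  expect_true(all(mf$table$s2_tilde >= lo - 1e-12))
  expect_true(all(mf$table$s2_tilde <= hi + 1e-12))
  expect_true(all(mf$table$q >= 0 & mf$table$q <= 1, na.rm = TRUE))
})

test_that("null scan is calibrated and finds nothing", {
  set.seed(86)
  scores <- matrix(rnorm(2000 * 22), 2000)
  ind <- factor(rep(1:11, each = 2))
  mf <- moderated_f_scan(scores, ind)
  ks <- suppressWarnings(stats::ks.test(mf$table$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(nrow(mf$regions), 2)
})

test_that("planted variable bins are detected and merged into regions", {
  set.seed(87)
  n <- 300
  ind <- rep(1:11, each = 2)
  scores <- matrix(rnorm(n * 22), n)
  hot <- 101:110
  for (b in hot) {
    mu <- rnorm(11, 0, 2)  # strong individual effect
    scores[b, ] <- mu[ind] + rnorm(22, 0, 0.5)
  }
  mf <- moderated_f_scan(scores, factor(ind))
  sig <- which(!is.na(mf$table$q) & mf$table$q < 0.1)
  expect_gte(length(intersect(sig, hot)), 8)
  expect_true(any(mf$regions$start_bin <= 101 & mf$regions$end_bin >= 108))
})

test_that("region merging is maximal and idempotent", {
  r <- merge_adjacent_bins(c(1, 2, 3, 7, 9, 10))
  expect_equal(r$start_bin, c(1, 7, 9))
  expect_equal(r$end_bin, c(3, 7, 10))
  again <- merge_adjacent_bins(unlist(Map(seq, r$start_bin, r$end_bin)))
  expect_equal(again, r)
})

# --- empirical FDR ----------------------------------------------------------

test_that("bootstrap FDR: reproducible, ~1 or NA on null, small on signal", {
  set.seed(88)
  ind <- factor(rep(1:8, each = 2))
  null_scores <- matrix(rnorm(300 * 16), 300)
  e1 <- empirical_fdr(null_scores, ind, n_boot = 20, seed = 5)
  e2 <- empirical_fdr(null_scores, ind, n_boot = 20, seed = 5)
  expect_identical(e1$boot_counts, e2$boot_counts)
  expect_true(is.na(e1$fdr) || e1$fdr > 0.5)

  sig_scores <- null_scores
  idx <- rep(1:8, each = 2)
  for (b in 1:30) {
    mu <- rnorm(8, 0, 3)
    sig_scores[b, ] <- mu[idx] + rnorm(16, 0, 0.5)
  }
  es <- empirical_fdr(sig_scores, ind, n_boot = 20, seed = 6)
  expect_lt(es$fdr, 0.2)
})

# --- cell variability + IHW-lite --------------------------------------------

test_that("within-zero/between-positive decomposition on exact replicates", {
  ind <- factor(rep(1:4, each = 2))
  cells <- matrix(rep(c(1, 5, 9, 13), each = 2), 1, byrow = TRUE)
  res <- cell_variability_scan(cells, ind, distance_bp = 1e6)
  expect_equal(res$var_within, 0)
  expect_gt(res$var_between, 0)
})

test_that("IHW-lite equals BH with a single stratum", {
  set.seed(89)
  p <- runif(500)^2
  q1 <- varhic:::ihw_adjust(p, covariate = rep(1, 500))
  expect_equal(q1, p.adjust(p, "BH"))
})

test_that("informative covariate weighting does not lose discoveries", {
  set.seed(90)
  # signal concentrated at short distances: covariate is informative
  d <- runif(2000, 0, 28e6)
  p <- runif(2000)
  short <- d < 5e6
  p[short] <- rbeta(sum(short), 0.2, 5)
  q_bh <- p.adjust(p, "BH")
  q_ihw <- varhic:::ihw_adjust(p, d)
  expect_gte(sum(q_ihw < 0.1), sum(q_bh < 0.1))
})

test_that("planted variable cells are recovered with FDP control", {
  set.seed(91)
  n_cells <- 1000
  ind <- rep(1:8, each = 2)
  cells <- matrix(rnorm(n_cells * 16), n_cells)
  hot <- sample(n_cells, 100)
  for (c in hot) {
    mu <- rnorm(8, 0, 2)
    cells[c, ] <- mu[ind] + rnorm(16, 0, 0.5)
  }
  d <- runif(n_cells, 0, 20e6)
  res <- cell_variability_scan(cells, factor(ind), d, fdr = 0.1)
  called <- which(res$significant)
  recall <- length(intersect(called, hot)) / length(hot)
  fdp <- if (length(called)) mean(!(called %in% hot)) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdp, 0.2)
})

test_that("cells beyond the distance cap are not tested", {
  ind <- factor(rep(1:3, each = 2))
  cells <- matrix(rnorm(12), 2, 6)
  res <- cell_variability_scan(cells, ind, distance_bp = c(1e6, 30e6))
  expect_true(res$tested[1])
  expect_false(res$tested[2])
  expect_true(is.na(res$q[2]))
})

# --- correlation with external tracks ---------------------------------------

test_that("monotone external signal gives rho 1 and minimal permutation p", {
  set.seed(92)
  feature <- matrix(rnorm(20 * 8), 20)
  external <- exp(feature)  # strictly monotone transform
  regions <- data.frame(start_bin = c(2, 10), end_bin = c(4, 12))
  res <- correlate_with_tracks(regions, feature, external, n_perm = 200,
                               seed = 3)
  expect_true(all(res$table$rho == 1))
  expect_lte(res$p, 1 / 100)
})

test_that("independent noise gives calibrated permutation p-values", {
  set.seed(93)
  ps <- vapply(1:40, function(i) {
    feature <- matrix(rnorm(10 * 8), 10)
    external <- matrix(rnorm(10 * 8), 10)
    regions <- data.frame(start_bin = c(1, 5), end_bin = c(2, 6))
    correlate_with_tracks(regions, feature, external, n_perm = 100,
                          seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("planted correlation at variable regions exceeds the null band", {
  set.seed(94)
  n <- 60; n_ind <- 14
  feature <- matrix(rnorm(n * n_ind), n)
  regions <- data.frame(start_bin = seq(1, 51, 10),
                        end_bin = seq(1, 51, 10))
  target <- regions$start_bin
  external <- simulate_epigenome_tracks(feature, target, rho = 0.8,
                                        seed = 95)
  res <- correlate_with_tracks(regions, feature, external, n_perm = 400,
                               seed = 96)
  expect_gt(res$median_rho, stats::quantile(res$perm_medians, 0.975))
})

test_that("consecutive variable bins collapse to the strongest external bin", {
  set.seed(95)
  feature <- matrix(rnorm(5 * 6), 5)
  external <- matrix(rnorm(5 * 6, 0, 0.2), 5)
  external[2, ] <- external[2, ] + 5   # dominant signal inside the run
  res <- correlate_with_tracks(data.frame(start_bin = 1, end_bin = 3),
                               feature, external, n_perm = 10, seed = 1)
  expect_equal(res$table$bin, 2L)
})

test_that("fewer than four individuals is an error", {
  expect_error(correlate_with_tracks(
    data.frame(start_bin = 1, end_bin = 1),
    matrix(rnorm(9), 3), matrix(rnorm(9), 3)), "4 individuals")
})

# --- reproducibility --------------------------------------------------------

test_that("pair counting: 20 individuals x 2 replicates", {
  ind <- rep(sprintf("i%02d", 1:20), each = 2)
  tracks <- matrix(rnorm(50 * 40), 50)
  res <- reproducibility_summary(tracks, ind)
  expect_equal(sum(res$pairs$group == "within"), 20L)
  expect_equal(sum(res$pairs$group == "between"), 760L)
})

test_that("identical samples give degenerate correlations and NA test", {
  tracks <- matrix(rep(rnorm(30), 4), 30)
  res <- reproducibility_summary(tracks, rep(c("a", "b"), each = 2))
  expect_equal(res$median_within, 1)
  expect_equal(res$median_between, 1)
  expect_true(is.na(res$p) || res$p == 1)
})

test_that("individual-specific structure separates within from between", {
  set.seed(97)
  n <- 200
  base <- rnorm(n)
  ind <- rep(1:6, each = 2)
  tracks <- sapply(seq_along(ind), function(k)
    base + rnorm(n, 0, 0.3) + 0.8 * sin(seq_len(n) / 5 + ind[k]))
  res <- reproducibility_summary(tracks, ind)
  expect_gt(res$median_within, res$median_between)
  expect_lt(res$p, 0.05)
})

test_that("matrix reproducibility works per distance band", {
  cfg <- sim_config(n_individuals = 3, seed = 98, chrom_length = 4e6)
  cms <- simulate_cohort_matrices(cfg, truth_set(cfg, comp_block = 25L),
                                  NULL)
  sheet <- cohort_sample_sheet(cfg)
  res <- matrix_reproducibility(cms, sheet$individual, max_band = 10)
  expect_equal(sort(unique(res$band)), 1:10)
  expect_equal(sum(res$band == 1), choose(6, 2))
})
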