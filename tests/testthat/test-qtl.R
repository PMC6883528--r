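# --- SNP selection ----------------------------------------------------------

test_that("MAF, carrier, and restriction-site filters", {
  # 11 discovery individuals; singleton alt -> MAF 1/22 < 0.05 -> dropped
  dos <- matrix(0, 3, 11)
  dos[1, 1] <- 1                         # singleton
  dos[2, ] <- c(rep(0, 5), rep(1, 6))    # common
  dos[3, ] <- c(rep(0, 5), rep(1, 6))    # common but on excluded position
  gt <- genotypes_from_dosages(dos, pos = c(100, 200, 300))
  ids <- sprintf("ind%02d", 1:11)
  out <- select_test_snps(gt, NULL, ids, hindiii_excl = 300)
  expect_identical(out$snp_id, "snp0002")
  expect_equal(out$maf, 6 / 22)
})

test_that("both alleles must be carried by at least two individuals", {
  dos <- matrix(0, 1, 11)
  dos[1, ] <- c(2, rep(0, 10))  # alt carried by 1 individual, MAF 2/22=0.09
  gt <- genotypes_from_dosages(dos)
  out <- select_test_snps(gt, NULL, sprintf("ind%02d", 1:11))
  expect_equal(nrow(out), 0L)
})

test_that("perfect-LD groups collapse to the smallest position", {
  v <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1)
  dos <- rbind(v, v, 2 - v)  # identical, identical, allele-swapped
  gt <- genotypes_from_dosages(dos, pos = c(500, 300, 800))
  out <- select_test_snps(gt, NULL, sprintf("ind%02d", 1:11))
  expect_equal(length(unique(out$ld_group)), 1L)
  expect_identical(out$pos[out$is_tag], 300)
  # no filters triggered: all three rows survive, one tag
  expect_equal(nrow(out), 3L)
})

test_that("empty discovery set is a configuration error", {
  gt <- genotypes_from_dosages(matrix(rep_len(0:1, 11), 1))
  expect_error(select_test_snps(gt, NULL, character(0)), "discovery")
})

# --- LMM fitting ------------------------------------------------------------

test_that("REML fitter matches lme4 on random instances", {
  skip_if_not_installed("lme4")
  set.seed(101)
  for (i in 1:20) {
    n <- 11
    id <- rep(seq_len(n), each = 2)
    g <- rep(sample(0:2, n, replace = TRUE), each = 2)
    if (sd(g) == 0) next
    y <- 0.7 * g + rep(rnorm(n, 0, 0.6), each = 2) + rnorm(2 * n, 0, 0.5)
    mine <- fit_lmm(y, g, id)
    ref <- lme4::lmer(y ~ g + (1 | id), REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    expect_equal(mine$beta[2], unname(lme4::fixef(ref)[2]), tolerance = 1e-3)
    expect_equal(mine$se, sqrt(as.numeric(vcov(ref)[2, 2])),
                 tolerance = 1e-2)
  }
})

test_that("LMM approaches OLS when the random effect vanishes", {
  # with subject_sd = 0 the REML variance ratio collapses to the boundary,
  # so beta and SE match OLS closely; p-values differ only through the
  # conservative t reference (df = N - n_ind - 1 instead of N - 2)
  set.seed(102)
  p_lmm <- c(); p_ols <- c(); b_diff <- c()
  for (i in 1:100) {
    n <- 11
    id <- rep(seq_len(n), each = 2)
    g <- rep(rbinom(n, 2, 0.3), each = 2)
    if (sd(g) == 0) next
    y <- 0.5 * g + rnorm(2 * n)   # subject_sd = 0
    fit <- fit_lmm(y, g, id)
    ref <- summary(stats::lm(y ~ g))$coefficients
    b_diff <- c(b_diff, abs(fit$beta[2] - ref[2, 1]))
    p_lmm <- c(p_lmm, fit$p); p_ols <- c(p_ols, ref[2, 4])
  }
  expect_lt(max(b_diff), 1e-8)                 # identical point estimates
  expect_gte(min(p_lmm - p_ols), -1e-8)        # never anticonservative
  expect_lt(median(p_lmm - p_ols), 0.03)       # close in probability
  expect_gt(cor(p_lmm, p_ols, method = "spearman"), 0.99)
})

test_that("noise-free genotype phenotype gives beta 1 and tiny p", {
  id <- rep(1:11, each = 2)
  g <- rep(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1), each = 2)
  fit <- fit_lmm(g + 0, g, id)   # phenotype equals dosage
  expect_equal(fit$beta[2], 1, tolerance = 1e-8)
  expect_lt(fit$p, 1e-12)
})

# --- scans and calling ------------------------------------------------------

test_that("type-I error of the scan is calibrated at the nominal level", {
  set.seed(103)
  n_tests <- 1000
  rej <- 0
  id <- rep(1:11, each = 2)
  for (i in seq_len(n_tests)) {
    g <- rbinom(11, 2, runif(1, 0.1, 0.5))
    while (sd(g) == 0) g <- rbinom(11, 2, 0.3)
    y <- rep(rnorm(11, 0, 0.5), each = 2) + rnorm(22, 0, 0.5)
    if (fit_lmm(y, g[id], id)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_tests, 0.03)
  expect_lte(rej / n_tests, 0.07)
})

test_that("planted effect size is recovered without bias", {
  set.seed(104)
  betas <- vapply(1:200, function(i) {
    g <- rbinom(11, 2, 0.35)
    while (sd(g) == 0) g <- rbinom(11, 2, 0.35)
    id <- rep(1:11, each = 2)
    y <- 1.0 * g[id] + rep(rnorm(11, 0, 0.5), each = 2) +
      rnorm(22, 0, 0.5)
    fit_lmm(y, g[id], id)$beta[2]
  }, numeric(1))
  expect_lt(abs(median(betas) - 1), 0.15)
})

test_that("lmm_scan ties bins to their SNPs and reports inflation", {
  set.seed(105)
  n_bins <- 30
  dose <- rbinom(11, 2, 0.4)
  while (sd(dose) == 0) dose <- rbinom(11, 2, 0.4)
  sim <- simulate_phenotypes(n_bins, dose, beta_at = 5, beta = 2,
                             subject_sd = 0.3, residual_sd = 0.3, seed = 9)
  dos <- matrix(rep(dose, n_bins), n_bins, byrow = TRUE)
  # also one constant SNP to exercise skipping
  dos[7, ] <- 2
  gt <- genotypes_from_dosages(dos, bin = seq_len(n_bins))
  snps <- select_test_snps(gt, NULL, sprintf("ind%02d", 1:11),
                           maf_min = 0)
  scan <- lmm_scan(sim$scores, snps, sim$individual)
  expect_true(5 %in% scan$table$bin)
  hit <- scan$table[scan$table$bin == 5, ]
  expect_lt(hit$p, 1e-4)
  expect_gt(hit$beta, 1)
  expect_true(all(c("median_p", "lambda") %in% names(scan$inflation)))
})

test_that("constant-genotype SNPs are skipped with a reason", {
  dos <- matrix(1, 2, 11)
  gt <- genotypes_from_dosages(dos, bin = 1:2)
  gt$maf <- 0.5; gt$bin <- 1:2; gt$ld_group <- 1:2; gt$is_tag <- TRUE
  scores <- matrix(rnorm(2 * 22), 2)
  scan <- lmm_scan(scores, gt, sprintf("ind%02d", rep(1:11, each = 2)))
  expect_equal(nrow(scan$table), 0L)
  expect_true(all(scan$skipped$reason == "constant genotype"))
})

test_that("QTL calling: FDR, best SNP per bin, DI class split", {
  scan <- list(table = data.frame(
    snp_id = c("a", "b", "c", "d"),
    bin = c(1, 1, 2, 3),
    pos = c(50, 10, 99, 120),
    beta = c(1, 1, -2, 0.5),
    se = 1, p = c(1e-6, 1e-4, 1e-5, 0.9), converged = TRUE))
  out <- call_qtls(scan, "FIRE", fdr = 0.2)
  expect_equal(nrow(out), 2L)             # bins 1 and 2
  expect_identical(out$snp_id[out$bin == 1], "a")  # smaller p wins
  expect_identical(out$direction, c("increase", "decrease"))

  # all p = 1 -> empty
  null_scan <- list(table = data.frame(
    snp_id = "x", bin = 1, pos = 1, beta = 0, se = 1, p = 1,
    converged = TRUE))
  expect_equal(nrow(call_qtls(null_scan, "FIRE")), 0L)

  # DI classes adjusted separately
  di <- classify_di_bins(cbind(c(15, -3), c(2, -20)))
  expect_identical(di, c("upstream", "downstream"))
})

test_that("tie on p is broken by smallest position", {
  scan <- list(table = data.frame(
    snp_id = c("far", "near"), bin = c(1, 1), pos = c(900, 100),
    beta = c(1, 1), se = 1, p = c(1e-6, 1e-6), converged = TRUE))
  out <- call_qtls(scan, "INS", fdr = 0.2)
  expect_identical(out$snp_id, "near")
})

test_that("call_qtls is invariant to SNP input order", {
  set.seed(106)
  tab <- data.frame(snp_id = paste0("s", 1:20),
                    bin = rep(1:5, each = 4),
                    pos = sample(1e5, 20), beta = rnorm(20), se = 1,
                    p = runif(20)^3, converged = TRUE)
  a <- call_qtls(list(table = tab), "FIRE")
  b <- call_qtls(list(table = tab[sample(20), ]), "FIRE")
  expect_equal(a[order(a$bin), ], b[order(b$bin), ], ignore_attr = TRUE)
})

# --- contact QTLs -----------------------------------------------------------

test_that("C-QTL scan tests only SNPs in anchor bins and recovers a plant", {
  set.seed(107)
  n_ind <- 11
  dose <- rbinom(n_ind, 2, 0.4)
  while (sd(dose) == 0 || sum(dose > 0) < 2 || sum(dose < 2) < 2)
    dose <- rbinom(n_ind, 2, 0.4)
  id <- rep(1:n_ind, each = 2)
  n_cells <- 40
  cells <- matrix(rnorm(n_cells * 22, 0, 0.5), n_cells)
  cells[10, ] <- cells[10, ] + 2 * dose[id]    # planted contact QTL
  anchors <- data.frame(anchor_i = seq_len(n_cells),
                        anchor_j = seq_len(n_cells) + 5)
  dos <- rbind(dose, matrix(rep(rbinom(n_ind, 2, 0.3), 3), 3, byrow = TRUE))
  gt <- genotypes_from_dosages(dos, bin = c(10, 200, 201, 202))
  snps <- select_test_snps(gt, NULL, sprintf("ind%02d", 1:n_ind),
                           maf_min = 0)
  res <- cqtl_scan(cells, anchors, snps,
                   sprintf("ind%02d", id), fdr = 0.2)
  # the planted SNP sits in anchor bin 10 of cell 10 only
  expect_true(all(res$tests$cell %in% c(5, 10)))
  expect_true(10 %in% res$qtls$cell)
})

test_that("SNP in neither anchor bin is never tested", {
  dose <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1)
  gt <- genotypes_from_dosages(matrix(dose, 1), bin = 50)
  snps <- select_test_snps(gt, NULL, sprintf("ind%02d", 1:11), maf_min = 0)
  cells <- matrix(rnorm(22), 1)
  res <- cqtl_scan(cells, data.frame(anchor_i = 1, anchor_j = 3), snps,
                   sprintf("ind%02d", rep(1:11, each = 2)))
  expect_equal(nrow(res$tests), 0L)
})

# --- validation -------------------------------------------------------------

test_that("held-out validation recovers planted direction and calibrates", {
  set.seed(108)
  n_bins <- 40
  disc_dose <- t(replicate(n_bins, rbinom(11, 2, 0.4)))
  held_dose <- t(replicate(n_bins, rbinom(6, 2, 0.4)))
  all_dose <- cbind(disc_dose, held_dose)
  gt <- genotypes_from_dosages(all_dose, bin = seq_len(n_bins))
  held_ids <- sprintf("ind%02d", 12:17)
  id6 <- rep(12:17, each = 2)
  # held-out phenotype with the same direction of effect at QTL bins
  qtl_bins <- 1:15
  scores <- matrix(rnorm(n_bins * 12, 0, 0.4), n_bins)
  for (b in qtl_bins)
    scores[b, ] <- scores[b, ] + 1.2 * held_dose[b, id6 - 11]
  qtls <- data.frame(phenotype = "FIRE", bin = qtl_bins,
                     snp_id = gt$snp_id[qtl_bins],
                     pos = gt$pos[qtl_bins], beta = 1,
                     p = 1e-6, q = 0.01, direction = "increase")
  universe <- cbind(data.frame(bin = seq_len(n_bins), snp_id = gt$snp_id,
                               pos = gt$pos), gt[held_ids])
  res <- validate_qtls(qtls, scores, gt, sprintf("ind%02d", id6),
                       universe = universe, n_perm = 200, seed = 3)
  expect_gt(res$slope, 0.5)
  expect_lte(res$boot_p, 0.05)

  # pure-noise held-out phenotype: p not extreme
  noise <- matrix(rnorm(n_bins * 12), n_bins)
  res0 <- validate_qtls(qtls, noise, gt, sprintf("ind%02d", id6),
                        universe = universe, n_perm = 200, seed = 4)
  expect_gt(res0$boot_p, 0.01)
})

test_that("empty QTL set cannot be validated", {
  expect_error(validate_qtls(data.frame(), matrix(0, 1, 2),
                             genotypes_from_dosages(matrix(0:1, 1)),
                             c("ind01", "ind01")), "nothing to validate")
})

# --- aggregate submatrices --------------------------------------------------

test_that("identical matrices give zero contrast maps", {
  m <- matrix(5, 30, 30)
  mats <- list(m, m, m, m)
  targets <- data.frame(anchor_i = 15, anchor_j = 15)
  dosages <- matrix(c(0, 1, 1, 2), 1)
  res <- aggregate_submatrices(targets, mats, dosages, flank_bins = 3)
  expect_true(all(res$d21 == 0))
  expect_true(all(res$d10 == 0))
})

test_that("allele-dose boost shows up in the central cell of the contrast", {
  set.seed(109)
  hits <- 0
  for (rep_i in 1:20) {
    n <- 41
    dose <- c(0, 0, 1, 1, 2, 2)
    mats <- lapply(dose, function(g) {
      m <- matrix(rnorm(n * n, 10, 0.3), n, n)
      m[21, 21] <- 10 + 2 * g
      m
    })
    targets <- data.frame(anchor_i = 21, anchor_j = 21)
    res <- aggregate_submatrices(targets, mats, matrix(dose, 1),
                                 flank_bins = 5)
    centre <- res$d21[6, 6]
    flank_mean <- mean(res$d21[-6, -6])
    if (centre > 0 && centre > flank_mean) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("submatrices with NA and edge targets are discarded and counted", {
  m_ok <- matrix(1, 20, 20)
  m_na <- m_ok; m_na[10, 10] <- NA
  targets <- data.frame(anchor_i = c(10, 2), anchor_j = c(10, 2))
  dosages <- matrix(c(1, 2,
                      1, 2), 2, byrow = TRUE)
  res <- aggregate_submatrices(targets, list(m_na, m_ok), dosages,
                               flank_bins = 4)
  expect_equal(res$n_skipped, 1L)        # edge target
  # the NA submatrix belonged to the dose-1 individual: d21 undefined
  expect_equal(unname(res$n_used["d21"]), 0L)
})

# --- power ------------------------------------------------------------------

test_that("power is near alpha at beta 0 and saturates for huge effects", {
  p0 <- power_simulation(maf = 0.3, beta = 0, subject_sd = 0.5,
                         residual_sd = 0.5, n_sim = 1000, seed = 11)
  expect_gte(p0$power, 0.03)
  expect_lte(p0$power, 0.07)
  p1 <- power_simulation(maf = 0.5, beta = 5, subject_sd = 0.5,
                         residual_sd = 0.5, n_sim = 200, seed = 12)
  expect_gt(p1$power, 0.99)
})

test_that("power is monotone in effect size over a grid", {
  grid <- c(0, 0.25, 0.5, 1, 2)
  pw <- vapply(grid, function(b)
    power_simulation(maf = 0.4, beta = b, subject_sd = 0.5,
                     residual_sd = 0.5, n_sim = 300, seed = 13)$power,
    numeric(1))
  expect_true(all(diff(pw) >= -0.02))  # non-decreasing up to MC noise
  expect_gt(pw[5], pw[1])
})

test_that("power rejects invalid configurations", {
  expect_error(power_simulation(maf = 0.7, beta = 1, subject_sd = 1,
                                residual_sd = 1), "maf")
  expect_error(power_simulation(maf = 0.3, beta = 1, subject_sd = -1,
                                residual_sd = 1), "non-negative")
})
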