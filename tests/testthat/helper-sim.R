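# shared fixtures built in code

# small deterministic symmetric count matrix
toy_matrix <- function(n = 6, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- rpois(sum(up), lambda)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, bin_size = 40000L)
}

# covariate table with no unreliable bins
toy_covariates <- function(n, seed = 2) {
  simulate_bin_covariates(n, zero_fraction = 0, seed = seed)
}

# constant-covariate table (no bias to remove)
flat_covariates <- function(n) {
  data.frame(bin = seq_len(n), eff_len = rep(1000, n), gc = rep(0.5, n),
             mappability = rep(1, n))
}

# matrix that is an exact function of distance
distance_matrix <- function(n = 10, f = function(d) 100 / (d + 1)) {
  m <- outer(seq_len(n), seq_len(n), function(i, j) f(abs(i - j)))
  contact_matrix(m)
}

# replicate-level phenotype scores from the random-intercept generative
# model, with optional planted genotype effects at given bins
simulate_phenotypes <- function(n_bins, dose, beta_at = integer(0),
                                beta = 0, subject_sd = 0.5,
                                residual_sd = 0.5, n_rep = 2, seed = 1) {
  set.seed(seed)
  n_ind <- length(dose)
  id <- rep(seq_len(n_ind), each = n_rep)
  scores <- matrix(0, n_bins, n_ind * n_rep)
  for (b in seq_len(n_bins)) {
    u <- rnorm(n_ind, 0, subject_sd)
    eff <- if (b %in% beta_at) beta else 0
    scores[b, ] <- eff * dose[id] + u[id] + rnorm(n_ind * n_rep, 0,
                                                  residual_sd)
  }
  list(scores = scores, individual = sprintf("ind%02d", id))
}

# genotype table from explicit dosage matrix (snps x individuals)
genotypes_from_dosages <- function(dos, pos = NULL, bin_size = 40000L,
                                   bin = NULL) {
  n_snp <- nrow(dos)
  ids <- sprintf("ind%02d", seq_len(ncol(dos)))
  colnames(dos) <- ids
  if (is.null(pos)) {
    if (is.null(bin)) bin <- seq_len(n_snp)
    pos <- (bin - 1L) * bin_size + 100L + seq_len(n_snp)
  }
  cbind(data.frame(snp_id = sprintf("snp%04d", seq_len(n_snp)),
                   chrom = "chrS", pos = pos,
                   ref = "A", alt = "G", stringsAsFactors = FALSE),
        as.data.frame(dos))
}

ma0139_path <- function() {
  system.file("extdata", "MA0139.1.jaspar", package = "varhic")
}
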