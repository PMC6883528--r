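#' Read a JASPAR-format position frequency matrix
#'
#' Parses the standard JASPAR text format (header line starting with `>`,
#' then four rows `A [ ... ]` etc.), converts counts to per-column base
#' probabilities with an optional pseudocount, and records the consensus
#' base per column.
#'
#' @param path path to the `.pfm`/`.jaspar` file.
#' @param pseudocount added to every count before normalization (default 0).
#' @return list of class `pwm` with `probs` (4 x L matrix, rows A/C/G/T),
#'   `consensus` (character vector length L), and `name`.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  name <- sub("^>\\s*", "", lines[grepl("^>", lines)][1])
  if (is.na(name)) name <- basename(path)
  rows <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(rows) != 4) stop("malformed PFM: expected 4 base rows")
  parse_row <- function(s) {
    s <- gsub("^[ACGTacgt]\\s*", "", s)
    s <- gsub("\\[|\\]", "", s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  }
  counts <- do.call(rbind, lapply(rows, parse_row))
  bases <- toupper(substr(trimws(rows), 1, 1))
  if (!setequal(bases, c("A", "C", "G", "T")))
    stop("malformed PFM: base labels must be A, C, G, T")
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  counts <- counts + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  structure(list(probs = probs,
                 consensus = rownames(probs)[apply(probs, 2, which.max)],
                 name = name),
            class = "pwm")
}

#' Construct a PWM from a probability matrix
#' @param probs 4 x L matrix with rows A, C, G, T; columns must sum to 1.
#' @param name motif name.
#' @return object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  if (any(abs(colSums(probs) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(probs = probs,
                 consensus = rownames(probs)[apply(probs, 2, which.max)],
                 name = name),
            class = "pwm")
}

#' Key (high-information) motif positions
#'
#' Columns of the PWM where a single base has probability strictly greater
#' than `threshold`. SNPs at these positions can cleanly split alleles
#' into consensus-matching (strong) and non-matching (weak).
#'
#' @param pwm a `pwm` object.
#' @param threshold probability cutoff (default 0.75; strict inequality).
#' @return integer column indices.
#' @export
key_positions <- function(pwm, threshold = 0.75) {
  if (!inherits(pwm, "pwm")) stop("malformed PWM")
  which(apply(pwm$probs, 2, max) > threshold)
}

revcomp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[toupper(b)]
}

#' Classify SNPs in motif occurrences as motif-disrupting
#'
#' Maps each SNP to its motif column (reverse-complemented on
#' minus-strand occurrences), and emits a call only when the column is a
#' key position and exactly one of the two alleles matches the consensus
#' base: that allele is the strong (S) allele, the other the weak (W)
#' allele. SNPs outside any motif, at non-key columns, or with neither or
#' both alleles matching the consensus produce no call.
#'
#' @param snps data frame `snp_id`, `pos`, `ref`, `alt` (alleles on the
#'   forward genome strand).
#' @param motifs data frame `start`, `end`, `strand` (1-based inclusive
#'   motif occurrence coordinates; strand `"+"`/`"-"`); optional
#'   `motif_id`.
#' @param pwm a `pwm` object; occurrence width must equal PWM length.
#' @param threshold key-position probability cutoff.
#' @return data frame `snp_id`, `motif`, `column`, `strand`,
#'   `strong_allele`, `weak_allele`.
#' @export
classify_motif_snps <- function(snps, motifs, pwm, threshold = 0.75) {
  keys <- key_positions(pwm, threshold)
  L <- ncol(pwm$probs)
  out <- list()
  for (m in seq_len(nrow(motifs))) {
    if (motifs$end[m] - motifs$start[m] + 1L != L) next
    hits <- which(snps$pos >= motifs$start[m] & snps$pos <= motifs$end[m])
    for (h in hits) {
      col <- if (motifs$strand[m] == "+") snps$pos[h] - motifs$start[m] + 1L
             else motifs$end[m] - snps$pos[h] + 1L
      if (!col %in% keys) next
      a1 <- toupper(snps$ref[h]); a2 <- toupper(snps$alt[h])
      if (motifs$strand[m] == "-") {
        a1 <- revcomp_base(a1); a2 <- revcomp_base(a2)
      }
      cons <- pwm$consensus[col]
      match1 <- a1 == cons; match2 <- a2 == cons
      if (match1 == match2) next   # neither or both match: no S/W split
      strong <- if (match1) snps$ref[h] else snps$alt[h]
      weak <- if (match1) snps$alt[h] else snps$ref[h]
      out[[length(out) + 1]] <- data.frame(
        snp_id = snps$snp_id[h],
        motif = if ("motif_id" %in% names(motifs)) motifs$motif_id[m] else m,
        column = col, strand = motifs$strand[m],
        strong_allele = strong, weak_allele = weak)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(0), motif = character(0),
               column = integer(0), strand = character(0),
               strong_allele = character(0), weak_allele = character(0))
}

#' Loop strength versus motif genotype
#'
#' For each loop/SNP, individuals are classified WW/WS/SS by their dose of
#' the strong (consensus) allele; loop strengths are normalized so the WS
#' class mean is 1 for that SNP, and the normalized strengths are pooled
#' into a single linear regression on S-allele dose. Loops without
#' heterozygous individuals cannot be normalized and are excluded (and
#' counted).
#'
#' @param strengths loops x individuals matrix of loop interaction values
#'   (quantile-normalized contact values at the loop's bin pair).
#' @param s_dose loops x individuals matrix of strong-allele doses
#'   (0/1/2; NA dropped).
#' @return list with `data` (pooled normalized values with dose), `slope`,
#'   `p`, `n_loops_used`, `n_excluded`.
#' @export
loop_genotype_regression <- function(strengths, s_dose) {
  strengths <- as.matrix(strengths); s_dose <- as.matrix(s_dose)
  stopifnot(all(dim(strengths) == dim(s_dose)))
  rows <- list(); excluded <- 0L
  for (l in seq_len(nrow(strengths))) {
    d <- s_dose[l, ]; y <- strengths[l, ]
    ok <- !is.na(d) & !is.na(y)
    het <- ok & d == 1
    if (!any(het) || mean(y[het]) == 0) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(loop = l, dose = d[ok], value = y[ok] / mean(y[het]))
  }
  if (!length(rows)) stop("no loops with heterozygous individuals")
  dat <- do.call(rbind, rows)
  if (stats::sd(dat$dose) == 0)
    return(list(data = dat, slope = 0, p = NA_real_,
                n_loops_used = length(rows), n_excluded = excluded))
  fit <- stats::lm(value ~ dose, data = dat)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(data = dat, slope = unname(sm[2, 1]), p = unname(sm[2, 4]),
       n_loops_used = length(rows), n_excluded = excluded)
}

#' Allelic imbalance of loop reads in heterozygotes
#'
#' Per (loop, heterozygous individual) with at least `min_total` loop
#' reads, computes the fraction of reads on the strong-allele haplotype
#' and tests whether the mean fraction exceeds 0.5 with a one-sided
#' one-sample t test.
#'
#' @param counts data frame with `s_count`, `w_count` (reads on the S and
#'   W haplotypes) per data point; other columns are carried through.
#' @param min_total minimum total loop reads to keep a data point
#'   (default 10).
#' @return list with `data` (retained points and `s_fraction`),
#'   `mean_fraction`, `t`, `p` (NA when everything is filtered),
#'   `n_used`, `n_filtered`.
#' @export
allelic_imbalance <- function(counts, min_total = 10L) {
  tot <- counts$s_count + counts$w_count
  keep <- !is.na(tot) & tot >= min_total
  kept <- counts[keep, , drop = FALSE]
  if (!nrow(kept))
    return(list(data = kept, mean_fraction = NA_real_, t = NA_real_,
                p = NA_real_, n_used = 0L, n_filtered = sum(!keep)))
  kept$s_fraction <- kept$s_count / (kept$s_count + kept$w_count)
  if (stats::sd(kept$s_fraction) == 0) {
    mf <- mean(kept$s_fraction)
    return(list(data = kept, mean_fraction = mf,
                t = if (mf == 0.5) 0 else Inf * sign(mf - 0.5),
                p = if (mf == 0.5) 0.5 else as.numeric(mf < 0.5),
                n_used = nrow(kept), n_filtered = sum(!keep)))
  }
  tt <- stats::t.test(kept$s_fraction, mu = 0.5, alternative = "greater")
  list(data = kept, mean_fraction = mean(kept$s_fraction),
       t = unname(tt$statistic), p = tt$p.value,
       n_used = nrow(kept), n_filtered = sum(!keep))
}
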