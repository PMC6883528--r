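---
title: "Population variability and QTL mapping for 3D chromatin phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population variability and QTL mapping for 3D chromatin phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varhic)
```

# Overview

`varhic` implements a population-scale analysis of 3D chromatin
conformation from binned Hi-C contact matrices: per-sample chromatin
phenotypes (compartment PC1, directionality index, insulation score,
FIRE score, TADs), cross-sample normalization and bandwise batch
correction, detection of inter-individual variability at bins and matrix
cells, linear-mixed-model QTL mapping with validation and power
machinery, CTCF motif-disruption loop analysis, and the nominal-fraction
sharing statistic. Because raw population Hi-C data are far too large
for routine testing, the package ships a synthetic cohort generator with
planted ground truth; every stage of the pipeline is exercised and
calibrated against what was planted.

This vignette explains the models, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic cohort does and does not demonstrate about real data.

# Contact-matrix processing

Read pairs are tallied into symmetric per-chromosome matrices on 0-based
half-open 40-kb bins, keeping the trailing partial bin; tiling the 22
hg19 autosomes this way yields the canonical 72,036 bins
(`autosome_bin_count()`).

**Covariate normalization** (`hicnorm()`). Raw counts of off-diagonal
cells are modelled as Poisson with
$\log \mathbb{E}[c_{ij}] = \beta_0 + \beta_1 \log(L_i L_j) +
\beta_2 \log(G_i G_j) + \log(M_i M_j)$, where $L$, $G$, $M$ are
effective fragment length, GC content and mappability; mappability
enters as an offset. The normalized value is observed/fitted. Bins with
any covariate equal to zero are unmappable and become NA rows/columns.
Distance deliberately does not enter the model; the distance structure
is handled downstream by the observed/expected transform.

**Quantile normalization** (`quantile_normalize()`). Each sample's
non-NA values are replaced by the mean of the order statistics across
samples at the same rank; ties receive the average of the tied reference
values and samples with unequal NA counts are mapped through
interpolated reference quantiles. This removes depth differences while
forcing a common marginal distribution.

**O/E transform** (`oe_transform()`). Each entry is divided by the mean
non-NA value at the same anchor distance within the same matrix, so the
mean O/E at every distance is exactly 1.

# Per-sample 3D phenotypes

**Directionality index** (`directionality_index()`). For bin $i$ with
upstream window sum $A$ and downstream window sum $B$ (window 2 Mb; the
QTL searches use a 200-kb variant to capture local structure),
$\mathrm{DI} = \mathrm{sign}(A-B)\,(A-B)^2/(A+B)$, the signed two-cell
chi-square statistic. Positive DI means upstream bias — note that some
other implementations use the opposite sign. Bins whose windows contain
more than 5 unusable bins (bins beyond the chromosome end count as
unusable) or no contacts at all are NA. "Strong" directionality means
$|\mathrm{DI}| > 10.82757$, the $\chi^2_1$ critical value at $p=0.001$
(`di_strong_threshold()`).

**Insulation score** (`insulation_score()`). On the O/E matrix, the mean
of the cells linking the upstream and downstream 400-kb flanks of a bin
divided by the mean over bin pairs inside the flanks (diagonal
excluded), truncated at 1, so 0 is absolute insulation and 1 no
insulation. The ratio could alternatively be min–max rescaled per
chromosome; truncation is the default because it keeps the score
comparable across chromosomes, and both are exposed through `rescale`.
Bins whose window has more than 50% NA cells, or which sit closer than
one window to the chromosome end, are NA.

**Compartment PC1** (`compartment_pc1()`). The O/E matrix is transformed
to a Pearson correlation matrix over bins and the eigenvectors of its
covariance are computed. The first eigenvector usually captures A/B
compartmentalization, but can instead track chromosome arms; a
chromosome is therefore accepted only when eigenvector 1 has the highest
absolute correlation with gene density among the first three, and the
sign is oriented so that positive PC1 means higher gene density
(compartment A). Gene density plays no role in the eigen decomposition
itself — it is only an orientation and quality-control track.

**FIRE score** (`fire_cis_counts()`, `fire_scores()`). Per bin, raw
contacts at anchor distances 15–200 kb are summed (sub-15-kb pairs
removed), normalized per sample with the same Poisson covariate model in
its cis form, quantile normalized across samples, transformed with
$\log_2(x+1)$, and z-scored per sample. A bin is a FIRE bin in a sample
when $z > \Phi^{-1}(0.95)$ (one-sided $p < 0.05$).

**TAD calling** (`call_tads()`). A 3-state hidden Markov model
(downstream bias, no bias, upstream bias) with Gaussian emissions is fit
to the DI track by EM and decoded with Viterbi; a boundary is called at
every switch from the upstream-bias state to the downstream-bias state.
Numerical choices that proved necessary:

* emissions are fitted on an asinh-compressed DI scale. DI is a
  chi-square statistic whose tails grow with sequencing depth, and
  single-Gaussian emissions on the raw scale let one state degenerate
  into a heavy-tailed background component. The transform is odd and
  monotone, so the upstream/downstream structure is untouched;
* state identity is anchored during EM (state-1 mean $\le 0 \le$
  state-3 mean, state-2 mean pinned at 0), which removes label-switching
  local optima;
* the three states share one emission SD, preventing a single wide
  state from swallowing the other states' data;
* self-transition prior 0.9, EM tolerance $10^{-6}$, at most 200
  iterations, initialization from the DI sextiles. NA bins contribute
  likelihood 1 (missing observations), so the path through NA stretches
  is determined by the transition structure alone.

# Bandwise normalization and batch correction

`bnbc_correct()` conditions on genomic distance throughout: for each
matrix band (all cells at one anchor distance), the samples'
log2 counts-per-million values (CPM per chromosome per sample, log
offset 0.5) are quantile normalized across samples, and known batches
are regressed out with a parametric empirical-Bayes location/scale
adjustment (normal prior on per-cell batch means, inverse-gamma on
per-cell batch variances; both mean and variance corrected). The 8 most
distal bands hold too few cells to estimate batch parameters and are set
to 0, as is the diagonal. Batches with a single sample stop the run with
an error; `drop_singleton_batches = TRUE` instead drops those samples,
mirroring the practice of excluding replicates that are alone in their
processing batch.

One point deserves emphasis for anyone evaluating the correction: after
correcting batch $b$, a test of corrected values against $b$ itself is
degenerate — the procedure removed exactly the quantity being tested, so
those p-values concentrate near 1 for *any* effective correction. The
meaningful checks, both implemented in the test suite, are (i) a planted
per-band shift of 1 log2 unit is reduced below 0.05, (ii) on a cohort
with no true batch effect the known-batch test shows no excess of small
p-values, and (iii) p-values against a partition of samples *not used in
the correction* remain uniform, i.e. the correction introduces no
spurious group structure.

# Inter-individual variability

**Moderated F scan** (`moderated_f_scan()`). Per bin, a one-way
fixed-effects fit of the replicate-level score on individual; residual
variances are shrunk with the empirical-Bayes estimator
$\tilde{s}^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with $(d_0,
s_0^2)$ obtained by closed-form moment matching on $\log s^2_g$
(digamma/trigamma inversion, $d_0$ clamped to $(0, 10^6]$); the
moderated F is tested on $(k-1,\, d_0+d_g)$ df, BH-adjusted at FDR 0.1,
and adjacent significant bins are merged into variable regions. The
hyperparameter estimates agree with limma's to machine precision, and
forcing $d_0 = 0$ reproduces the ordinary ANOVA exactly — both are
pinned by tests. `empirical_fdr()` rebuilds the scan on replicate
columns resampled with replacement (which breaks the replicate–
individual pairing) and reports mean background hits / observed hits.

**Testability filters** (`select_testable_bins()`). FIRE: called FIRE in
any replicate; DI: strong bias in any replicate; INS: per-sample z-score
below −1 in any replicate; PC1: no metric filter. Then exclusions:
unreliable-covariate bins plus a 200-kb margin, configured regions such
as the MHC locus, and bins near structural variants longer than 10 kb
with metric-specific flanks (FIRE 200 kb, INS 400 kb, DI 2 Mb, PC1
direct overlap).

**Matrix cells** (`cell_variability_scan()`). Cells closer than 28 Mb
are tested with the same one-way F; FDR control uses a covariate-
weighted BH ("IHW-lite"): cells are split into up to 10 equal-count
anchor-distance strata, each stratum weighted by its estimated non-null
proportion (Storey $\hat\pi_0$ at $\lambda = 0.5$, weights normalized to
mean 1), and BH applied to $p/w$. The stratum count shrinks so that
every stratum keeps at least 50 tests — $\hat\pi_0$ estimated on a
handful of tests is noise and destroys rather than adds power. With one
stratum the procedure is exactly BH. Effect sizes come from the balanced
one-way variance decomposition into between-individual (biological) and
within-individual (technical) components.

**External tracks** (`correlate_with_tracks()`). Runs of consecutive
variable bins collapse to the bin with the strongest external signal;
Spearman correlations across individuals are summarized by their median
and referred to a null built by permuting the individual labels of the
external data (two-sided via $|$median$|$, 10,000 permutations by
default).

# QTL mapping

**SNP selection** (`select_test_snps()`). Biallelic SNPs, restriction-
site polymorphism positions removed, MAF $\ge$ 0.05 in the discovery
set with both alleles carried by at least 2 individuals, assigned to
their 40-kb bin and restricted to testable bins; within each bin,
perfect-LD groups (identical dosage vectors up to a global allele swap,
computed on discovery individuals) collapse to the smallest-position tag
SNP, a deterministic choice that keeps the scan reproducible.

**The model** (`fit_lmm()`, `lmm_scan()`). Replicate-level score
$y_{ij} = \alpha + \beta g_i + u_i + \varepsilon_{ij}$ with a random
intercept per individual, fitted by REML. The variance ratio is profiled
out and optimized on the log scale; everything else is closed-form
because the random-intercept covariance inverts blockwise, which makes a
fit cheap enough for tens of thousands of Monte-Carlo refits. The Wald
test on $\beta$ uses a t reference with df $= N - n_{\mathrm{ind}} - 1$,
a deliberately conservative convention (the point estimates and SEs
match lme4's REML to $10^{-4}$; the df convention makes the p-values
slightly larger than large-sample ones). Each scan reports its
genomic-inflation summary (median p, $\lambda$).

**Calling** (`call_qtls()`). BH within phenotype at FDR 0.2; DI bins are
first classified upstream/downstream by the sign of the largest-|DI|
value among discovery individuals and the two classes adjusted
separately, avoiding a Simpson's-paradox artifact; the best SNP per bin
(smallest p, ties by position) is reported. Contact QTLs
(`cqtl_scan()`) test variable cells against tag SNPs in either anchor
bin, use the distance-weighted FDR, and report the most significant SNP
per cell, replaced by the leftmost member of its perfect-LD group across
the two anchors.

**Validation** (`validate_qtls()`). Held-out individuals' phenotypes are
pooled across QTLs with dosages oriented to the discovery direction of
effect and regressed on dose; the null re-draws the same number of
random (bin, SNP) pairs from the testable universe 1000 times.

**Power** (`power_simulation()`). Dosages are sums of two binomial
allele draws; responses follow the same generative LMM (2 replicates per
subject); power is the rejection fraction of the same Wald test at
$\alpha = 0.05$ over 1000 runs.

# CTCF motifs and loops

Key PWM positions are columns where one base exceeds probability 0.75
(strict). On the JASPAR MA0139.1 CTCF matrix shipped as a plain-text
fixture this yields 8 positions. A SNP in a motif occurrence is
classified by its motif column (reverse-complemented on minus-strand
occurrences); a call requires a key column and exactly one allele
matching the consensus — that allele is the strong (S) allele. Loop
strengths are normalized per SNP so the heterozygote class mean is 1,
pooled, and regressed on S-allele dose. Allelic imbalance uses the
fraction of haplotype-assigned loop reads on the S haplotype among
(loop, heterozygote) points with at least 10 reads, tested with a
one-sided t test against 0.5.

# Nominal-fraction sharing

For QTL set Y and association scan X, the nominal fraction is the share
of Y SNPs with X-scan $p < 0.05$; significance comes from a 2×2
chi-square against the non-QTL tested SNPs (no continuity correction by
default) and from a permutation null drawing $|Y|$ SNPs from the tested
universe (without replacement within a draw, independent across draws;
10,000 draws). Cell-level scans are first reduced to each SNP's minimum
p. For external summary statistics the QTL set and the control universe
are both extended with perfect-LD partners before comparison, and the
enrichment ratio (QTL fraction / universe fraction) is reported. The
permutation p is conservative on its discrete support — the fraction
moves in steps of $1/|Y|$ and ties count toward rejection — so under the
null it is valid ($P(p \le \alpha) \le \alpha$) rather than exactly
uniform; the calibration tests check precisely that property.

# The synthetic cohort

`sim_config()` + `truth_set()` + `simulate_cohort_matrices()` emulate a
20-individual, two-replicate lymphoblastoid cohort on one synthetic
16-Mb chromosome of 400 40-kb bins (large enough for the 2-Mb DI window,
small enough for desk-scale tests). The expected intensity of cell
$(i,j)$ multiplies: power-law distance decay (exponent 1), a compartment
checkerboard ($\exp(c\,v_i v_j)$ with $c = 0.3$ over alternating 2-Mb
blocks), within-TAD enrichment (factor 2, domains of 20 bins),
short-range FIRE boosts (factor 2 at 5% of bins over the 15–200-kb
scoring range), focal loops (factor 3), planted genotype effects
(per-dose log-scale effects on FIRE-range contacts, cross-boundary
contacts, upstream/downstream asymmetry, or single cells), and per-band
log-scale batch distortions (SD 0.3 for the second batch). Counts are
Poisson — matching the Poisson normalization model — with optional
gamma overdispersion, scaled to 5×10⁵ expected read pairs per replicate.
Replicates of an individual share all genotype-driven structure and
differ only by sampling and batch. All randomness flows from the single
config seed through fixed offsets (genotypes +1, covariates +2,
replicate matrices +3…, epigenome tracks +101, haplotype reads +102), so
identical configs are byte-identical.

What passing tests show — and what they do not. The generator produces
the *phenomena* the pipeline measures (decay, compartments, TADs,
FIREs, loops, additive genotype effects, band-wise batch structure), so
recovery tests demonstrate that each statistic detects what it claims to
detect at realistic effect sizes and depths. The generator does not
emulate restriction-fragment geometry, mappability artifacts, trans
contacts, translocations, population stratification, or LD structure
beyond planted perfect-LD pairs; conclusions about robustness to those
features require real data.

Two evaluation conventions worth noting. TAD-boundary recovery is scored
over planted boundaries where the 2-Mb DI window fits inside the
chromosome — bins within about 45 bins of either end have NA DI by the
window rule, so boundaries there are invisible to any DI-based caller on
a finite chromosome. The QTL recovery studies plant effects of 1.2 per
alt dose against subject and residual SDs of 0.5 (about 1.7 observation
SDs), with 60 targets, 12 planted, MAF 0.4, 11 individuals × 2
replicates, and each contact cell carrying exactly one test SNP in one
anchor bin; measured over repeated seeds the bin-level and cell-level
scans recall ≈0.92–0.93 of planted effects at FDR 0.2 with observed
false-discovery proportion ≈0.15–0.18.

# Problem sizes and defaults

| Quantity | Default | Where |
|---|---|---|
| bin size | 40 kb | throughout |
| DI window | 2 Mb (QTL variant 200 kb) | `directionality_index` |
| INS window | 400 kb (QTL variant 200 kb) | `insulation_score` |
| FIRE range | 15–200 kb | `fire_cis_counts` |
| strong DI | 10.82757 ($\chi^2_1$, $p=10^{-3}$) | `di_strong_threshold` |
| FIRE call | $z > \Phi^{-1}(0.95)$ | `fire_scores` |
| variable-bin FDR | 0.1 | `moderated_f_scan` |
| cell distance cap | 28 Mb | `cell_variability_scan` |
| QTL FDR | 0.2 | `call_qtls`, `cqtl_scan` |
| discovery set | 11 individuals × 2 replicates | QTL scans |
| distal zeroed bands | 8 | `bnbc_correct` |
| key-position cutoff | 0.75 (strict) | `key_positions` |
| min loop reads | 10 | `allelic_imbalance` |
| permutations | 10,000 (correlation/sharing), 1,000 (bootstrap FDR / validation) | various |

The test suite and the acceptance script run these methods at reduced
problem sizes (400-bin chromosomes, 25–50 seeds, hundreds of
permutations), chosen so the full suite completes in a few minutes on a
single core while leaving the statistical conclusions stable across
seeds.

# Known limitations

* The HMM simplifies the original mixture-of-Gaussians emissions to
  single (shared-SD) Gaussians; very noisy DI tracks may shift
  boundaries by a bin.
* The Wald df convention is conservative rather than Satterthwaite;
  with 11 individuals this costs a little power relative to dedicated
  mixed-model testing tools.
* IHW-lite implements covariate weighting, not the full IHW convex
  optimization; its guarantees are those of weighted BH.
* `hicnorm()` follows the original covariate model (no distance term);
  matrices dominated by distance-dependent bias should be O/E
  transformed before interpretation.
* The variance decomposition for cell effect sizes uses balanced-design
  moment estimators, which coincide with ML only for equal replicate
  counts.
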