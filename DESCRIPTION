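Package: varhic
Title: Population Variability and QTL Mapping for 3D Chromatin Phenotypes from Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for population-scale analysis of 3D chromatin conformation
    from binned Hi-C contact matrices. Computes per-sample chromatin
    phenotypes (A/B compartment PC1, directionality index, insulation score,
    FIRE score, and TAD calls), performs covariate-based Poisson
    normalization, cross-sample quantile normalization and bandwise batch
    correction, detects bins and matrix cells with inter-individual
    variability using moderated F statistics and covariate-weighted FDR,
    maps FIRE/DI/INS/contact QTLs with a random-intercept linear mixed
    model including held-out validation and Monte Carlo power analysis,
    quantifies CTCF motif-disruption effects on chromatin loop strength,
    and measures sub-genome-wide sharing between association scans via the
    nominal-fraction statistic. Ships a synthetic Hi-C cohort generator
    with planted compartments, TADs, FIREs, loops, batch effects and
    genotype effects so the full pipeline can be exercised and calibrated
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    limma,
    sva,
    jsonlite
Config/testthat/edition: 3
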