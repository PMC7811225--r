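Package: PeriodicCN
Title: Tumor Purity, Ploidy and Allele-Specific Copy Number from Low-Coverage
    Tumor/Normal Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers tumor purity, ploidy, total copy number (TCN) and
    allele-specific copy number (ASCN) of somatic copy-number alterations from
    binned read counts of a matched tumor/normal pair plus allele counts at
    heterozygous germline SNVs. Per-bin Tumor Read Enrichment (TRE) values are
    kernel-smoothed, segmented with a sparse-Bayesian-learning (GADA-style)
    changepoint model, and the periodic spacing of the TRE histogram -- detected
    by autocorrelation -- seeds an EM fit of a lattice-tied Gaussian mixture
    whose parameters are purity, ploidy and per-segment integer copy states;
    models are compared by BIC. Major/minor allele copy numbers of clonal
    segments are assigned from log ratios of allelic coverage ratios (LAR) with
    an exact truncated-binomial correction for the exclusion of
    zero-allele-coverage SNVs. Includes a count-level tumor/normal simulator
    (single-clone and two-subclone designs) and the CallF/FullC concordance
    metrics for benchmarking copy-number callers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    GenomicRanges
Imports:
    methods,
    stats,
    utils,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
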