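Package: rvassoc
Title: Rare-Variant Gene-Level Association Testing and Interpretation for
    Case-Control Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed workflow for rare-variant association
    analysis of case-control exome sequencing studies. Provides seeded
    synthetic multi-ancestry cohorts with realistic allele-frequency
    spectra and gene architectures (allelic series, single drivers, mixed
    direction); severity-mask construction over per-transcript variant
    annotations; Firth-penalized, score, and kinship-adjusted single-variant
    tests with fixed-effect and sample-size-weighted meta-analysis; burden,
    SKAT, and inactivation-weighted gene-level tests consolidated by a
    minimum-P procedure corrected for the effective number of masks;
    matched-gene set enrichment and direction-of-effect concordance tests;
    liability-variance-explained and case-control power calculations with
    an exponential rank-model extrapolation; and a concordance-calibrated
    posterior-probability-of-association method with Bayes-factor gene
    priors and beta-uniform mixture prior estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
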