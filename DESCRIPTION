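Package: hybriq
Title: Quantitative Hybrid Detection and Culling-Threshold Optimization
    from Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative management of hybridization between two
    diverged taxa genotyped at microsatellite loci. Provides GenePop and
    STRUCTURE-table genotype I/O, allele-frequency and diversity summaries,
    individual-level PCA, calibrated synthetic parental reference pools,
    pedigree hybrid-class simulation (F1, F2, backcrosses, double
    backcrosses), a two-cluster admixture model (Gibbs sampler with
    uncorrelated or correlated allele frequencies, plus a deterministic EM
    estimator), genotype-frequency-class posterior classification into
    pedigree categories, species-specific diagnostic-allele rules, and
    efficiency/accuracy/performance evaluation of ancestry-coefficient
    thresholds with removal-consequence curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
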