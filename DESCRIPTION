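Package: admixscan
Title: Local Ancestry Deviation and Haplotype-Based Selection Scans in Admixed Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recently admixed cohorts from phased exome
    genotypes: a tract-based admixed-cohort simulator with known ground truth
    (Balding-Nichols ancestral panels, Markov ancestry mosaics, optional
    locally inflated ancestry), deterministic exome QC filters with a removal
    ledger, population structure (PCA, AMOVA with permutation phi-statistics,
    inversion-karyotype clustering), local-ancestry summarisation and regional
    deviation detection, a five-statistic positive-selection scan (iHS, delta-iHH,
    XP-EHH, cross-population delta-iHH, PBS on Hudson's Fst) combined into a
    Fisher combined score with block-level outlier calling, and allele-frequency
    and pathogenicity-prediction summaries for candidate regions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    mclust,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
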