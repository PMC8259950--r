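Package: tbpsnp
Title: TBP-Promoter Affinity Scoring of Regulatory SNPs with Selection and
    Domestication Cross-Validation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores TATA-binding protein (TBP) affinity of 70-bp core
    promoters with a position-weight-matrix plus dinucleotide-context
    sliding-window model, compares promoter alleles of candidate
    regulatory SNPs (Fisher Z-score, deficiency/excess verdicts), maps
    verdicts to disease-direction markers through a curated gene catalog,
    tests marker tallies for neutral drift versus selection with exact
    binomial statistics, and cross-validates marker directions against
    domestic-versus-wild differential-expression tables using 2x2
    contingency statistics (Pearson chi-square, Fisher exact, row
    binomials).  Includes seeded synthetic-data generators for
    calibration and end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
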