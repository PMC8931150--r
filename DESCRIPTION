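Package: cnvsex
Title: Copy-Number-Based Molecular Sexing for X0/XX Insects by qPCR and ddPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the dosage of an X-linked target gene against an
    autosomal reference gene to sex individuals of species with X0/XX sex
    determination (males carry one X, females two). Supports droplet digital
    PCR (Poisson inversion of droplet counts to template concentrations) and
    real-time PCR (standard-curve amplification efficiencies and
    calibrator-relative Pfaffl quantification), classifies specimens as male
    (copy number near 1) or female (near 2), and provides the associated
    assay-validation statistics: descriptive summaries, bimodality amplitude,
    paired t-tests on biological replicates, Shapiro-Wilk normality, the phi
    association coefficient against known sexes, and a chi-square test of the
    1:1 sex ratio. A synthetic-data module simulates Ct tables and droplet
    counts with run effects and technical-replicate noise so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
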