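Package: ampliscope
Title: Dose-Dependent Rates of Antibiotic Resistance Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how fast antibiotic resistance evolves as a function of
    drug dose. Implements two-strain selection-coefficient models that predict
    an inverted-U relationship between dose and the rate of adaptation,
    including mutant-selection-window boundaries and closed-form hotspot doses;
    growth-curve model fitting with AICc selection and blank correction for
    plate-reader OD/GFP timeseries; Hill dose-response fits with MIC (IC99) and
    effective-antibiotic-dose (EAD) statistics; phenotypic rate-of-adaptation
    statistics and oscillation periodograms; genomic selection proxies for gene
    copy-number amplifications from longitudinal coverage data and for SNPs
    from allele-frequency trajectories, with a between-treatment parallelism
    coefficient; and a synthetic-data generator that emulates serial-transfer
    evolution experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
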