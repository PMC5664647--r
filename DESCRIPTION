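Package: pathgei
Title: Candidate Gene-Pathway Gene-Environment Interaction Analysis via
    Logic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-step framework for testing gene-environment
    interactions (GEIs) on a candidate gene pathway. Step 1 summarises each
    gene's SNP genotypes into a Boolean gene-specific tree (GST) by logic
    regression (simulated-annealing search over AND/OR trees of
    dominant/recessive indicators, with cross-validated model-size
    selection); Step 2 builds pathway trees over the GSTs; Step 3 fits
    adjusted logistic (case-control risk) and stage-stratified Cox
    (survival) models with GST-by-exposure interaction terms, summarises
    sub-pathways by backward selection, jointly tests the survivors, and
    corrects for multiple testing by permuting GST and exposure columns.
    A synthetic-data generator emulates the genotype, exposure and outcome
    structure of a case-control study with planted interaction effects so
    the whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
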