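Package: rubicap
Title: Carbon and Redox Accounting for Rubisco-Based CO2 Capture Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the CO2-uptake flux of engineered Escherichia coli strains
    that run a phosphoribulokinase/Rubisco bypass from the fraction of
    13C-labeled d-lactate, partitions xylose consumption between the pentose
    phosphate pathway and the bypass, and closes carbon-atom and NADH balances
    for resting-cell capture fermentations. Also fits Michaelis-Menten
    carboxylation kinetics with uncertainties, quantifies Rubisco expression
    from CABP-titrated active sites (percent of cellular soluble protein,
    specific activity, turnover number), propagates measurement uncertainty by
    Monte Carlo, and generates synthetic fermentation time courses and kinetic
    assays with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
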