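Package: physflux
Title: Physiological Shrinkage and Sampling of Metabolic Flux Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of metabolic models with physiological
    flux-phenotype bounds. Fits glucose-uptake-dependent linear bands for
    oxygen, ethanol and glycerol exchange from chemostat flux-phenotype
    tables, applies them to a stoichiometric model, predicts growth-rate
    envelopes by flux balance analysis, uniformly samples the shrunken
    steady-state flux polytope with an artificial-centering hit-and-run
    chain, and computes per-reaction average flux, flux fluctuation and flux
    constraint strength. Downstream statistics link flux fluctuation to gene
    expression noise: dosage-sensitive reaction selection, essentiality
    grouping, Spearman correlation and permutation tests. Includes
    synthetic-data generators for flux tables, toy stoichiometric networks
    and expression/noise datasets with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
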