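Package: FoldRateBench
Title: External Validation of Protein Folding Rate Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking protein folding rate predictors the way
    QSAR/QSPR models are validated. Builds provenance-aware overlap and
    difference subsets of kinetics datasets matched by PDB code, fits
    chain-length baseline models of the form ln(kf) = a0 + a1*ln(L) with a
    minimal length-range applicability domain, computes RMSE/PCC/MAE in
    fitting, leave-one-out cross-validation and external-prediction modes
    (for fitted baselines and for ingested third-party predictions alike),
    quantifies experimental-data discrepancies between datasets that share
    PDB codes, maps fitted models onto their transition-state-theory
    interpretation, and generates synthetic kinetics datasets with known
    ground truth so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
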