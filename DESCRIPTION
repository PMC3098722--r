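Package: evls
Title: Post-Processing and Benchmarking of Ensemble Virtual Ligand Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing multi-conformer ("ensemble") docking
    virtual screens. Merges per-conformer score tables with best-score and
    best-rank combination protocols (and documented alternatives), evaluates
    the separation of binders from decoys with five early-recognition figures
    of merit (AUAC, ROC AUC, enrichment factor, RIE, BEDROC), benchmarks
    ensemble against single-conformer performance by percentile placement and
    paired one-tailed tests, quantifies chemotype diversity in the top-ranked
    fraction, and applies cognate-ligand and all-positive-score conformer
    filters. A synthetic score-matrix generator with explicit induced-fit
    structure stands in for the docking engine so every stage can be exercised
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
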