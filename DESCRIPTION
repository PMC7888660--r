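Package: imodulonr
Title: Consensus Independent Component Analysis of Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes bulk transcriptomic compendia into independently
    modulated gene sets (iModulons) and their condition-dependent activities.
    Provides quality-control filtering and reference-condition centering of
    multi-dataset compendia, a consensus ICA decomposition (multi-restart
    FastICA with density-based clustering of components and cross-repetition
    agreement), statistical extraction of each component's significant gene
    set by iterative D'Agostino K-squared thresholding, regulon and gene-set
    enrichment with FDR control, reciprocal-best-hit comparison of component
    structures across datasets, pseudoinverse projection of expression
    contrasts onto component activities with per-component explained
    variance, and a synthetic compendium generator with planted regulatory
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
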