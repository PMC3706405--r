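Package: metascale
Title: Hierarchical Space-Time Scale Analysis of Metacommunity Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hierarchically organized temporal species groups in
    metacommunity monitoring series and tests whether each temporal scale
    carries a commensurate spatial and environmental signal. Time is modeled
    with principal coordinates of neighbour matrices (PCNM/dbMEM
    eigenfunctions) related to Hellinger-transformed community tables by
    redundancy analysis with double-stopping forward selection and sequential
    permutation tests of canonical axes. Taxa and environmental variables
    correlating with each modeled group trend are compiled into time-explicit
    correlation matrices, which are partitioned into pure spatial, pure
    environmental, shared and residual fractions (adjusted R-squared, partial
    redundancy analysis permutation tests). Includes a dispersal-trait
    comparison of group-contributing taxa and a synthetic metacommunity
    generator with planted multi-scale temporal structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
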