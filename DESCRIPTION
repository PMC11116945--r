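Package: nemastruct
Title: Metacommunity Structure Analysis for Soil Nematode Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Elements of metacommunity structure (EMS) analysis for
    site-by-genus community tables: reciprocal-averaging ordination,
    coherence (embedded absences), turnover (replacements) and boundary
    clumping (Morisita's index) with null-model significance tests and the
    full structure classification including quasi-structures. Also provides
    C-score/SES co-occurrence analysis under a fixed-fixed sequential-swap
    null, Mantel tests relating Bray-Curtis community dissimilarity to
    environmental and geographic distance, permutation-importance
    regression of ordination site scores on environmental and spatial
    variables, and generators of synthetic metacommunities with known
    structure that emulate a multi-site, multi-land-cover soil nematode
    survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    randomForest,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
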