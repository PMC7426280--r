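Package: gardendiv
Title: Alpha and Beta Diversity Analysis for Paired-Site Arthropod Inventories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising and comparing arthropod communities
    sampled at two sites: Hill-series alpha diversity (Shannon exponential,
    inverse Simpson, inverse Berger-Parker), nonparametric richness
    estimation (Chao1, first-order jackknife) with sample-based accumulation
    curves, completeness ratios and final-slope diagnostics, individual-based
    rarefaction, partitioning of total beta diversity (Jaccard) into species
    replacement and richness-difference components for incidence and
    abundance data, dominance-set extraction at the 50 percent threshold, and
    a randomization test for differences in Berger-Parker dominance. Includes
    a synthetic paired-community generator with log-series abundances for
    testing and simulation, and a pipeline that produces report tables from a
    long-format occurrence file.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
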