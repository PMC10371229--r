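Package: irfinger
Title: Genetic Fingerprinting of Muscle Insulin Resistance and Compound Reversal Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning proteomic and metabolic phenotyping of a
    genetically diverse (Diversity Outbred style) mouse population into a
    causal molecular fingerprint of insulin resistance, and for ranking
    candidate reversal compounds. Implements the Matsuda Index
    insulin-sensitivity surrogate, covariate-adjusted protein-trait
    association with Storey q-values, kinship-aware protein QTL scans with
    permutation significance thresholds and cis/trans classification,
    fingerprint construction (negative association intersected with
    cis-pQTL presence), a weighted Kolmogorov-Smirnov enrichment core shared
    by GSEA and drug-signature connectivity scoring, GLUT4-translocation
    screen hit calling, and z-score integration into an overall compound
    ranking. Ships a fully deterministic synthetic-data generator with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
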