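Package: herbqc
Title: Fingerprint Similarity, Chemometric Ranking, Response-Surface
    Optimization and LC-MS Annotation for Herbal Decoction Standardization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for standardizing multi-herb aqueous
    decoctions. Aligns chromatographic peak tables across batches by a
    retention-time window, builds median reference fingerprints and scores
    batch similarity; ranks batch quality with correlation-matrix PCA
    comprehensive scores and hierarchical clustering; fits and optimizes
    coded-unit quadratic models on three-factor Box-Behnken designs with
    desirability aggregation and lack-of-fit ANOVA; and annotates LC-MS
    compounds and plasma metabolites by exact monoisotopic mass, adduct and
    ppm arithmetic, neutral-loss fragmentation ladders, and
    biotransformation mass shifts (glucuronidation, sulfation,
    demethylation, hydroxylation). Includes deterministic synthetic-data
    generators emulating each input so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
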