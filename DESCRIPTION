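Package: psilc
Title: Pathway-Cluster Survival Signatures and Contextual Synthetic
    Lethality for Lobular Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery-validation workflow for pathway-centric prognostic
    modelling of invasive lobular breast cancer transcriptomes. Identifies
    differentially expressed and differentially variable genes between
    tumour and normal tissue, maps them onto pathway gene sets by
    over-representation analysis, collapses redundant pathways into
    clusters of pathways (CPs) via overlap-coefficient hierarchical
    clustering with silhouette-guided cluster-number selection, fits
    per-CP Cox proportional-hazards risk scores with discovery-derived
    risk-group cut-offs, aggregates CP scores into a multivariable random
    survival forest (PSILC) tuned by out-of-bag error, tests risk-group by
    chemotherapy interactions, and screens CRISPR gene-effect profiles for
    dependencies selective to high-risk cell lines. Includes a synthetic
    cohort generator with planted ground truth so every stage is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    ranger,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
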