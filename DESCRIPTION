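Package: emtime
Title: Pan-Cancer EMT Scoring and Tumor Immune Microenvironment Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a 16-marker epithelial-mesenchymal transition (EMT)
    score from per-gene z-scored bulk expression, stratifies tumor cohorts
    into EMT-high/intermediate/low quartile groups, and profiles the tumor
    immune microenvironment (TIME) across groups: immune-cell enrichment
    scores, checkpoint and cytokine gene expression, and mean-z gene
    signatures are contrasted by median-difference landscapes,
    two-sample Kolmogorov-Smirnov tests, one-way ANOVA and Spearman
    correlation; cohorts are classified by PCA and silhouette-selected
    K-means on high-minus-low delta profiles; overall survival and
    progression-free interval are compared between EMT groups with
    Kaplan-Meier estimation and log-rank tests. Includes a seeded
    synthetic-cohort generator with planted ground truth so the entire
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
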