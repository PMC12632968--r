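Package: trajswitch
Title: Temporal Trajectory Clustering and Cross-Condition Cluster
    Switching for Developmental RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters stage-mean expression trajectories from developmental
    time-course RNA-seq and quantifies how cluster membership changes
    between experimental conditions. Implements a prevalence-based CPM
    expression filter, gene-wise Z-scoring, stage-mean profile
    construction, seeded multi-restart k-means with a within-cluster
    sum-of-squares sweep and an elbow selection rule, nearest-centroid
    projection of a comparison condition onto reference-trained clusters,
    and transition (alluvial) tables of cluster switching. Also provides
    delta-delta-Ct relative quantification for mitochondrial DNA copy
    number, targeted bisulfite amplicon percent-methylation summaries,
    gene-set intersection utilities, and a negative-binomial count
    simulator with planted trajectory archetypes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
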