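Package: oabnet
Title: Dynamic Network Analysis of Longitudinal Overactive Bladder Symptom Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters patients on their five-timepoint overactive bladder
    symptom score (OABSS) trajectories, builds per-timepoint patient
    similarity networks from Pearson correlations with a reciprocal
    edge-length transform, and tracks per-cluster network statistics
    (average degree centrality, edge density) over 24 months of follow-up.
    Includes a calibrated synthetic cohort generator with planted response
    clusters, Ward/elbow/K-means cluster selection, 2-component PCA
    embedding, change-from-baseline summary tables, and a reproducible
    end-to-end pipeline with CSV/GraphML/YAML interfaces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
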