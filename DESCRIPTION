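Package: segdyn
Title: Dynamic Brain-Network Segregation During Feedback-Driven Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the transition from integrated to
    segregated whole-brain functional network states during feedback-driven
    stimulus-response learning. Implements tapered sliding-window weighted
    Pearson connectivity, two-state city-block k-means brain-state
    clustering with system-segregation labelling, signed weighted Louvain
    community detection with consensus partitioning and modularity-Q
    trajectories, node cartography (participation coefficient and
    module-degree z-score), closed-form drift-diffusion model estimation of
    learning rate and habit strength from two-choice trials, and the
    cohort-level brain-behaviour statistics linking network segregation
    dynamics to behaviour. Includes a synthetic-cohort generator with known
    ground truth (state-switching region time series coupled to
    drift-diffusion behaviour) for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
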