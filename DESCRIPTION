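Package: mogp
Title: Mixture of Gaussian Processes for Clustering Disease-Progression
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters sparse, irregularly sampled longitudinal clinical
    scores (such as ALSFRS-R, its subscores, or forced vital capacity) into
    groups of patients with similar disease-progression patterns, using a
    Dirichlet-process mixture of Gaussian processes with a monotonic-decline
    inductive bias and an onset anchor. Includes patient-specific linear
    slope and two-parameter sigmoid benchmarks, a linear-kernel mixture
    benchmark, interpolation/forecasting/transfer evaluation harnesses,
    Kaplan-Meier survival correspondence with pairwise logrank tests, a
    synthetic-cohort generator with ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
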