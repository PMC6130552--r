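Package: fadconn
Title: Two-Group Comparison of Functional and Structural Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructs functional (Fisher-z correlation) and structural
    (streamline-count thresholded, FA-weighted) brain connectomes from
    region-level time series and tractography tables, measures graph-theoretic
    properties (characteristic path length, clustering, small-worldness,
    efficiency, modularity) across proportional density thresholds and on
    weighted graphs with rewired-null normalization, and tests group
    differences by windowed-AUC permutation tests, density-covaried linear
    models, truncated power-law degree-distribution fits, the network-based
    statistic with family-wise error control, and structure-function coupling
    via communication-measure regression. Includes a synthetic two-group
    cohort generator so the full pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
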