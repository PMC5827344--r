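Package: fearspace
Title: Searchlight Cross-Decoding of Conditioned and Phobic Fear Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether fear conditioning moves the multivariate
    activation pattern of a conditioned stimulus toward that of a pre-existing
    phobic stimulus, and back after extinction. Implements the full analysis
    chain: a synthetic-data generator with controllable representational
    geometry (event schedules with partial shock reinforcement and geometric
    inter-trial jitter, per-trial pattern maps, BOLD-like time series),
    single-trial general linear models yielding t-score maps, 50-voxel
    volumetric searchlight cross-decoding with a regularized linear
    discriminant classifier trained on neutral-versus-phobic patterns and
    tested on conditioned-stimulus patterns, per-voxel quadratic regression of
    the three-phase decoding profile, sign-flip Monte Carlo inference with
    threshold-free cluster enhancement and max-statistic family-wise error
    control, cluster extraction, cosine-angle representational similarity with
    Fisher-transformed correlation follow-ups, and region-of-interest control
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
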