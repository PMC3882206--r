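Package: crosstx
Title: Cross-Species Transcriptomic Effect-Size Comparison and Age-Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative transcriptomics of diet interventions and
    species divergence: per-gene Cohen's d effect sizes for two-group contrasts,
    Pearson comparison of effect-size vectors across datasets with binomial and
    label-permutation meta-tests, permutation-based FDR detection of
    diet-affected genes (Welch t / Mann-Whitney U), spline-based age-trajectory
    interpolation over species-specific developmental and aging windows,
    cross-species trajectory pattern classification (conserved / level-shifted /
    shape-divergent), k-means expression modules with permutation effect tests,
    gene-set correlation screens, and dynamic-time-warping alignment of
    developmental time series with bootstrap confidence intervals for
    corresponding ages. Includes synthetic-data generators with known ground
    truth for every stage, probe-level detectability filtering against
    GC-matched background, and quantile normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    limma,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
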