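Package: microstates
Title: EEG Microstate Segmentation and Bayesian Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis for routine clinical
    recordings: preprocessing (band-pass filtering, eyes-closed segment
    selection, average referencing, single bad-channel interpolation,
    alpha-dominance quality control), polarity-invariant modified K-means
    clustering of topographies at global field power peaks with
    silhouette-based selection of the number of maps, two-level
    (subject-then-group) clustering, backfitting of reference maps with
    temporal smoothing, per-subject occurrence/coverage/mean-duration
    statistics and C/D imbalance ratios, and Bayesian two-group comparison
    (robust t model with a region of practical equivalence decision rule)
    alongside covariate-adjusted ANOVA. Includes a synthetic-cohort
    generator with known microstate ground truth so every stage can be
    validated by parameter recovery, and EDF+ input/output in a BIDS-like
    cohort layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    rjags,
    coda,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'layout.R'
    'synthetic.R'
    'edf.R'
    'preprocess.R'
    'microstate.R'
    'backfit.R'
    'inference.R'
    'pipeline.R'
    'plot.R'
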