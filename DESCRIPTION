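Package: collimap
Title: Retinotopic and Concentric Orientation Map Analysis for the Superior Colliculus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the functional organization of orientation
    preference in the superficial superior colliculus. Provides axial circular
    statistics with a permutation test for columnar clustering of orientation
    preference along electrode penetrations; tuning-curve indices (orientation
    index, direction selectivity index, von Mises fits) for unit recordings;
    stimulus-triggered dF/F map construction from wide-field calcium imaging
    stacks (retinotopy, polar orientation, ANOVA significance and
    single-condition maps); retinotopic geometry that turns patch-wise
    receptive field fits into per-pixel azimuth/elevation maps and a predicted
    concentric-orientation map; quantitative map comparison by circular
    correlation; and a synthetic-data generator with known ground truth for
    both imaging and electrophysiology modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
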