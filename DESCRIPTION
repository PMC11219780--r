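Package: keymarker
Title: Key-Marker Detection and a Composite Early-Warning Index from
    Neural-Network Weight Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects coherent modules of clinical indicators ("key markers")
    that drive a continuous outcome, and scores individual samples with a
    composite early-warning index. A three-layer backpropagation regression
    network is fitted to a samples-by-indicators table; the input-to-hidden
    weight profiles are clustered by single-linkage hierarchical clustering
    and the uppermost tail of the merge distances delineates the marker
    module. Module coherence is characterised by Spearman rank correlations,
    and a per-sample warning index (the ratio of the mean to the skewness of
    the row-standardized marker scores) flags samples with abnormal marker
    configurations before the outcome itself deviates. Includes KNN
    imputation and min-max scaling preprocessing, a seeded synthetic-cohort
    generator with a planted marker module and planted pre-onset anomalies,
    and a reproducible end-to-end pipeline with an artifact manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    minpack.lm,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bpnn.R'
    'correlation.R'
    'ewi.R'
    'io.R'
    'keymarker-package.R'
    'markers.R'
    'pipeline.R'
    'preprocess.R'
    'synthetic.R'
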