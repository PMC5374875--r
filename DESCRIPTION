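Package: adbn
Title: Discrete Bayesian Networks for Probabilistic Staging of Alzheimer's
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A small engine for discrete Bayesian networks over binary
    (absent/present) variables with categorical conditional probability
    tables and deterministic max (logical OR) aggregator nodes, in the
    style popularised by the WinBUGS 'dcat' formulation of medical
    diagnostic networks.  Provides exact inference by enumeration or
    variable elimination, ancestral and single-site Gibbs sampling with
    WinBUGS-style posterior summaries (mean, standard deviation,
    batch-means Monte Carlo error), and a reader/writer for WinBUGS-style
    data-list documents.  Ships a curated Alzheimer's disease biomarker
    network covering the eight diagnostic categories of the revised
    NINCDS-ADRDA research criteria, a registry of published biomarker
    risk rates, and four worked case studies bundled as verifiable
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
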