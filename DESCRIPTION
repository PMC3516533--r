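Package: hostsdm
Title: Coupled Species Distribution Models for Obligately Interacting Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble species distribution modelling for a species that
    obligately depends on a host, with three schemes for coupling the two
    species' projections (range overlap, host probability as an explanatory
    variable, and calibration restricted to the host's reference area),
    prevalence- and mean-probability thresholding, omission/commission and
    AUC evaluation, multivariate environmental similarity (MESS) screening
    for non-analogue climate, range-change accounting, and hierarchical
    partitioning of projection variance across algorithms and coupling
    schemes. Includes a virtual-species simulator that generates gridded
    climate and occurrence data with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rpart,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
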