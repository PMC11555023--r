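Package: tapjid
Title: Joint Interval Distributions and Cluster-Based Permutation Tests
    for Smartphone Touchscreen Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing smartphone touchscreen interaction
    dynamics as a behavioural time series. Raw tap timestamp streams are
    segmented into behavioural days by a nightly-gap rise-time heuristic,
    each day's inter-touch intervals are summarised as a joint interval
    distribution (JID; a 2D kernel density over consecutive log10
    intervals on a 50x50 grid), and groups of daily JIDs are compared
    with a cluster-based permutation test built on bin-wise t-statistics
    and a max-cluster-size null distribution. A seeded synthetic study
    generator emulates a months-long single-subject study with medication
    tapering and a convulsion day, so the full pipeline is testable
    without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
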