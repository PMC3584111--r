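Package: stnatlas
Title: Midcommissural Coordinate Frames and Fiducial-Stretch Registration
    for Deep-Brain Target Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for landmark-based stereotactic localization of deep-brain
    nuclei. Builds the midcommissural (AC-PC) head coordinate frame from
    anatomical landmarks and converts landmark sets between image-native and
    AC-PC coordinates; averages multiple specimen datasets into an atlas model
    of subthalamic-nucleus position; registers subject landmark sets to the
    atlas by per-axis fiducial stretch ratios; and quantifies red-nucleus
    localization error across a cohort under competing stretch schemes. A
    synthetic-cohort generator draws landmark sets from a multivariate normal
    model with configurable means, spreads and correlations, so the full
    pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
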