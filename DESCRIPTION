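Package: archolimb
Title: Evolution of Hindlimb Muscle Leverage Along the Archosaurian Bird-Line
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how hindlimb muscle-tendon-unit (MTU) leverage
    evolved along the archosaurian lineage to birds. Builds posable
    musculoskeletal limb models from bone point clouds and structured model
    specifications, computes signed muscle moment arms by the virtual-work
    method (with via points and cylinder/sphere/ellipsoid wrapping surfaces),
    sweeps joint ranges of motion and reduces curves to mean segment-length
    normalized moment arms, reconstructs ancestral character states under
    Brownian motion on a time-calibrated phylogeny with 95% confidence
    intervals, and runs the summed-moment-arm ratio and threshold analysis
    used to detect shifts between hip-based and knee-based locomotion.
    Includes seed-deterministic generators for synthetic limb models with
    analytically known moment arms and for Brownian trait evolution on the
    study tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
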