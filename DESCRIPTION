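Package: synaptometry
Title: Synaptic Precision and Information Capacity from Dendritic Spine
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of dendritic spine morphometry and the
    precision of synaptic plasticity. Generates synthetic spine populations
    with realistic cross-metric correlation structure and axon-coupled spine
    pairs, measures convex-hull head and neck volumes, surface areas and
    docked-vesicle counts from tagged triangulated meshes, computes per-pair
    coefficients of variation against random-pairing resampling nulls, and
    derives the number of discriminable synaptic strength levels (and bits of
    information per synapse) spanned by the observed dynamic range under a
    signal-detection model, together with the binomial release-averaging time
    windows required to read synaptic strength at a target precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
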