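Package: calcitrace
Title: In Situ Interferometry Analysis of Microbe-Mineral Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of time-lapse vertical scanning interferometry (VSI)
    records of microbial cells attached to dissolving mineral surfaces.
    Provides a virtual-interferometer generator with known ground truth
    (surface retreat, cell detachment schedules, under-cell dissolution
    inhibition), readers and writers for co-registered height/grayscale
    image stacks, cell segmentation from height-depression artifacts and
    grayscale contrast, residence-time mapping, retreat- and detachment-rate
    regression against an inert quartz reference, arithmetic mean roughness
    metrics, and an open-system carbonate speciation module that inverts
    observed dissolution-rate reductions into interfacial pH and calcite
    saturation state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
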