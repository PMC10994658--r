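Package: spiculeMorph
Title: 3D Morphometry of Sea Urchin Larval Spicules from Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry of calcite spicules from 3D micro-CT
    volumes of sea urchin larvae, together with the fluorescence and
    statistical analyses that accompany such studies. The package segments
    grayscale volumes into per-spicule label fields, extracts one-voxel-wide
    medial skeletons by topology-preserving thinning, organizes them into
    endpoint/junction graphs, and reports per-spicule volume, isosurface
    area, total branch length, distance-transform-based mean thickness and
    tip/junction counts. Companion modules quantify stained-pixel ratios and
    vesicle counts in fluorescence regions of interest, and compare cohorts
    with z, paired t and Kruskal-Wallis tests, fold changes and growth
    rates. A synthetic phantom generator renders capsule-shaped rods,
    triradiate and branched spicule geometries with analytic ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
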