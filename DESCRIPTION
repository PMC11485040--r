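Package: tractblue
Title: Protocol-Constrained Tractography, Connectivity Blueprints and
    Cross-Brain Divergence on Synthetic Phantom Brains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale machinery for testing multi-template white-matter
    tractography pipelines against known ground truth. Generates synthetic
    phantom brains (fibre-orientation fields supporting tube-shaped tracts,
    cortical surface meshes with parcellations, scalar maps, and smooth warp
    fields between template grids), runs protocol-constrained probabilistic
    streamline tractography with seed/waypoint/exclusion/stop semantics,
    audits ROI protocol sets (overlap, out-of-brain voxels, left-right
    asymmetry), compares tracts across template spaces (Pearson correlation
    of normalised path distributions, median FA/MD, population percentage
    atlases), builds cortex-by-tract connectivity blueprints from
    surface-seeded connectivity, and compares blueprints across brains with
    the symmetric Kullback-Leibler divergence (homologue identification and
    scalar-map projection). Results come back as tibbles with tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    xml2,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
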