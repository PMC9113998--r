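Package: walkshed
Title: Fine-Resolution Pedestrian Travel-Time Maps to Health Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs walking-speed cost allocation ("friction") surfaces
    from categorical land cover, road networks and topography, and estimates
    pedestrian travel time from every raster cell to the nearest health
    facility by multi-source least-cost-path analysis on a 20 m grid.
    Open water is treated as a barrier unless crossing it is the only way to
    reach a facility (a two-pass rule for island populations), slopes steeper
    than 100 percent are impassable, and all walking speeds can be reduced by
    a multiplicative factor to represent adults travelling with children.
    Includes GeoTIFF raster input/output, all-touched road rasterization with
    fastest-speed priority, slope-dependent speed weighting, facility
    validation and snapping with an audit report, deterministic synthetic
    scene generators, and a configuration-driven command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
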