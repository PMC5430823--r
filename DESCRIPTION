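Package: nanodomains
Title: Nanodomain Detection and Structure Analysis for Lipid Bilayer Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis suite for molecular-dynamics trajectories of planar
    lipid bilayers, aimed at detecting and characterizing cholesterol-driven
    membrane nanodomains. Computes deuterium order parameter (S_CD)
    distributions along acyl chains and decomposes heterogeneous systems into
    gel / liquid-ordered / liquid-disordered components by simplex-constrained
    least squares; builds periodic gridded maps of membrane thickness, chain
    order and lateral mobility; quantifies interleaflet registration of
    ordered regions; detects hexagonal chain packing from nearest-neighbour
    statistics and 2D radial distribution functions; classifies the membrane
    plane into core / ordered / disordered regions and tracks domain area in
    time; and detects cholesterol flip-flop events with a hysteresis detector,
    localizing them relative to the domain boundary. Includes a synthetic
    bilayer generator that produces GRO trajectories with known ground truth
    (region layout, target order, packing, registration, mobility, scripted
    flip-flops) so every analysis stage is verifiable without microsecond
    simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
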