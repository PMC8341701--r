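Package: cyclox
Title: Agent-Based Tissue Patches and Oxygen Dynamics for Radiology Voxels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the cellular and vascular architecture underlying a single
    radiology-image voxel and its oxygen dynamics. Generates off-lattice packings of
    vessels, tumor cells and stromal cells at prescribed area fractions via repulsive
    force relaxation, stabilizes a reaction-diffusion oxygen field with Michaelis-Menten
    cellular uptake to a numerically steady state, sweeps a library of tissue
    compositions classified by average pO2, and fits piecewise-constant vascular-influx
    or cellular-uptake schedules to measured short-time pO2 fluctuation series by
    mesh-adaptive pattern search, including robustness analysis of fitted schedules
    across morphologically distinct tissues with similar oxygenation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
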