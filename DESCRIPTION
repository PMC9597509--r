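Package: noripipe
Title: Simulation and Analysis of Normalized Raman Mass-Densitometry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for label-free single-cell dry-mass densitometry with
    three-band stimulated Raman scattering (SRS) microscopy. Generates
    synthetic cell populations with known protein, lipid and water densities
    and renders them as noisy SRS band images; spectrally unmixes band images
    into absolute concentration maps with a per-pixel volume-fraction
    normalisation (the NoRI algorithm); segments cell bodies, nuclei and
    nucleoli by density thresholds, Otsu's method and watershed splitting;
    quantifies per-cell compartment densities, masses and volumes; and
    provides the population statistics used in densitometry studies
    (coefficients of variation, variability decomposition, one-way ANOVA
    significance codes, fold changes to control medians, Hoechst cell-cycle
    gating, EdU gating, protein-synthesis ratios and a senescence caller).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
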