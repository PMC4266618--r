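Package: gliogrow
Title: Go-or-Grow Simulation of Glioblastoma Growth, Brain Invasion and
    Anti-Angiogenic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical-scale two-dimensional reaction-diffusion-advection
    simulator of glioblastoma built on the go-or-grow hypothesis:
    proliferative cells divide but do not move, invasive cells move but do
    not divide, and the local hypoxic state switches cells between the two
    phenotypes.  Invasive cells migrate by white-matter-weighted passive
    diffusion and by active transport up the healthy-brain density
    gradient; angiogenesis raises the hypoxic and lethal thresholds and
    anti-angiogenic therapy suppresses that rise.  The package provides
    brain-domain construction (raster import and a synthetic phantom),
    treatment protocols including an anti-angiogenic window and a transient
    vascular-normalization boost, matched-mass calibration of the two
    migration mechanisms, the standard readouts (cell masses, percent
    necrosis and invasion, layer radii, virtual-MRI label maps), parameter
    sweeps, and the accompanying clinical statistics: bidimensional lesion
    areas, least-absolute-residuals polynomial fits, Kaplan-Meier curves
    and log-rank tests, plus a synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
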