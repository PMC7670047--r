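Package: vesselgr
Title: Constrained-Mixture Growth and Remodeling of Arteries with Smooth
    Muscle Tone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of arterial growth and remodeling (G&R)
    based on the homogenized constrained mixture theory. An idealized
    two-layer (media/adventitia) thick-walled cylinder is built from
    elastin, four collagen fiber families and smooth muscle cells (SMCs),
    each with its own strain energy, deposition pre-stretch, mass turnover
    and remodeling law. SMC active tone follows an inverted-parabola
    length-tension relationship, allowing study of how variations in
    maximal contractility interact with localized elastin degradation and
    stress-driven collagen deposition during aneurysm progression.
    Provides homeostatic initialization of the loaded in-vivo state,
    monthly staggered time integration, sensitivity sweeps over damage
    time, collagen gain and maximal active stretch, and tidy accessors
    and plots for all results.
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
    minpack.lm,
    purrr,
    rlang,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
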