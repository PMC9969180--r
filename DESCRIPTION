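Package: muellerpol
Title: Mueller-Matrix Polarimetry of Optically Active Solutions and
    Mutarotation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse Mueller-matrix polarimetry of isotropic
    chiral liquids. Provides Jones and Mueller calculus for circular
    birefringence and circular dichroism, a Sellmeier/Drude dispersion model
    linking the gyration tensor element g11 to circular retardation and
    specific rotatory power, first-order mutarotation kinetics of reducing
    sugars, global spectral-temporal least-squares inversion that recovers
    branch-unwrapped absolute rotation spectra, mutarotation rate constants
    and per-anomer gyration spectra, and a synthetic-data generator that
    emulates broadband transmission Mueller ellipsometry of saccharide
    solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
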