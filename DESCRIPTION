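Package: autoflux
Title: Kinetic Modelling and Statistical Analysis of Autophagic Flux Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting autophagic vesicle counts from tandem
    fluorescent Atg8/LGG-1 reporter assays. Implements the three-step kinetic
    model of autophagy (isolation membrane to autophagosome to autolysosome to
    degradation) with closed-form and numerical time courses, steady-state pool
    and flux relations, inference of rate-constant fold-changes from paired
    control versus Bafilomycin A pool measurements, a flux classifier for
    BafA-response patterns, demonstration of flux non-identifiability from
    steady-state pools together with maximum-likelihood time-course fitting,
    Poisson-regression comparison of puncta counts, and a synthetic
    puncta-count generator emulating a full multi-tissue ageing study design
    in Caenorhabditis elegans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
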