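Package: nichebounds
Title: Quantifying Hutchinson's Niche Inequalities from Thermal Tolerances,
    Climate Grids and Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the chain of Grinnellian niche inclusions
    between a species' fundamental niche (a physiological thermal tolerance
    interval), its existing niche (the part of the fundamental niche actually
    available in the current climate) and its realized niche (the climates at
    observed occurrences). Models available environmental space with Gaussian
    kernel densities over an equal-area climate grid, tests occurrence
    placement against a binomial random-placement null with sequential
    Bonferroni (Holm) correction, measures niche overlap by integrating the
    minimum of two kernel densities, compares fundamental-niche volumes to a
    random-interval null model, and simulates virtual worlds and virtual
    species with known ground truth so the whole pipeline is testable end to
    end. Tibble-first API with broom-style tidiers and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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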