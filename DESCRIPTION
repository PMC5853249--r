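Package: papillastats
Title: Spatial Association of Remodelled Actin Bundles with Wall Ingrowth
    Papillae and Vesicle-Trafficking Arithmetic in Transfer Cells
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for studying wall ingrowth (WI) papilla
    construction in trans-differentiating transfer cells. Implements a
    Monte Carlo randomization test for spatial association between the ends
    of short, thin actin bundles and WI papilla centres (random re-placement
    of the observed bundles within the cell window, single-tail p-values),
    with per-cell results aggregated across a cohort; Brefeldin A baseline
    correction of FM4-64FX regional fluorescence tables and the derived
    trafficking statistics (regional totals, fold increase, percent decline,
    percent inhibition); a geometric plasma-membrane budget for exo- and
    endocytosis during papilla growth; morphometric helpers (wall thickness,
    remodelled-cell classification, papilla gap, bundle orientation, lagged
    time-course correlation); a transcript selection filter; and seeded
    synthetic-data generators emulating the measured geometry so every stage
    is testable without micrograph-derived coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
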