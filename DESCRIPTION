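Package: pmflie
Title: Binding Energetics of Beta-Sheet Aggregation Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for evaluating pseudo-peptide inhibitors of
    amyloid-beta aggregation from molecular-dynamics output: weighted
    histogram analysis (WHAM) reconstruction of umbrella-sampling potentials
    of mean force with Bayesian-bootstrap error bars, endpoint binding
    free-energy estimators (Gas-PBSA and the LIE-S/LIE-D/LIE-DR linear
    interaction energy family) with block-averaged uncertainties, the
    effective aggregation-disruption free energy (2 dG_R-PP - dG_RR -
    dG_PP-PP), and the conformational statistics reported per cluster:
    Kabsch RMSD, GROMOS-style RMSD-cutoff clustering, intermolecular
    hydrogen-bond counts, salt-bridge monitors, centre-of-mass separations
    and beta-sheet registry. A synthetic-data module generates harmonically
    biased reaction-coordinate samples, autocorrelated energy series and
    idealized beta-sheet conformer pairs so the full pipeline is testable
    without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
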