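Package: stsnet
Title: Spatio-Temporal Steering Diagnostics for Open Quantum Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spatio-temporal assemblages from measurements on one node
    of an open quantum network followed by Lindblad time evolution, and
    quantifies their steerability with two semidefinite-program measures, the
    spatio-temporal steering weight and robustness.  Both reduce to the
    Einstein-Podolsky-Rosen and temporal forms of steering in the appropriate
    limits.  Ships a three-qubit dephasing chain and a seven-site
    Fenna-Matthews-Olson (FMO) exciton-transfer model with reaction-center
    sink and Haken-Strobl dephasing as ready-made scenarios, deterministic
    hidden-state strategy enumeration, a compact primal-dual interior-point
    solver for the block-diagonal Hermitian semidefinite programs involved,
    steering scans over time grids, and JSON/YAML serialization of models,
    scenarios and assemblages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
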