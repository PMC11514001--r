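Package: dimergpr
Title: Per-Atom Gaussian Process Potentials for the Water Dimer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds machine-learned potentials for the gas-phase water dimer
    from per-atom Gaussian process regression on Atomic Local Frame (ALF)
    descriptors. Provides uniform configuration-space sampling of dimer
    geometries over a separation range, an analytic flexible-water surrogate
    potential with an exact atomic-energy partition for label generation,
    ARD kernels with periodic handling of azimuthal features, analytic
    Cartesian forces via descriptor Jacobians, and a simulation engine for
    damped-dynamics geometry optimization, Nose-Hoover NVT molecular
    dynamics, and rigid coordinate scans driven only by the model's
    predicted energies and forces. Includes S-curve and mean-absolute-error
    evaluation utilities and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, tools
Suggests: testthat (>= 3.0.0), withr, knitr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
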