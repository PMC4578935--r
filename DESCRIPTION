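Package: mubafire
Title: Multistage Background Field Removal for MR Field Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes background field contributions from magnetic resonance
    field maps prior to quantitative susceptibility mapping or phase-contrast
    analysis. Implements a sequential filter chain combining a first-order
    polynomial correction, projection onto solid spherical harmonics
    orthonormalized on an arbitrary masked domain, and projection onto dipole
    fields of an exterior pseudo-susceptibility solved by conjugate gradients,
    with an optional local outlier-exclusion stage for air-bubble-like
    distortions. Also provides a mask-aware Gaussian reference filter, a Monte
    Carlo brain-phantom simulator for validation, evaluation metrics, parameter
    sweeps, and NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pracma,
    jsonlite,
    yaml,
    optparse,
    ggplot2,
    rlang,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
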