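Package: chiroboost
Title: Transmission Circular Dichroism of Relativistically Moving Chiral
    Molecules from Dipolar T-Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale frame-hopping pipeline for the rotationally averaged
    transmission circular dichroism (TCD) of a chiral molecule moving at
    relativistic speed along the optical axis. Dipolar (6x6) transition
    matrices are built from bianisotropic dynamic polarizability tensors
    (electric-electric, electric-magnetic, magnetic-electric,
    magnetic-magnetic), rotated with Wigner-D matrices in the helicity basis,
    and driven by a Lorentz-boosted circularly polarized plane wave; forward
    transmissions for both incident helicities yield the TCD after inverse
    boosting to the observer frame. Includes a Thomson-style gradient-descent
    orientation sampler for uniform rotational averaging, absorption/ACD
    spectrum reconstruction from the same T-matrices, a synthetic generator of
    damped-Lorentzian chiral polarizability sets for end-to-end testing
    without quantum-chemistry input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
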