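Package: vwoxy
Title: Oxygen Mass Transfer and Hydrodynamics in Vertical-Wheel Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for surface-aerated Vertical-Wheel bioreactors:
    estimation of the liquid-side oxygen mass-transfer coefficient (kL, kLa)
    from luminescence-quenching aeration traces, fitting and application of a
    modified Sherwood correlation Sh = k*Re^alpha*Sc^(1/3)*G^gamma with a
    geometric volume-correction group G = D*A/V, oxygen-limited maximum
    cell-density prediction (OTR = OUR), and post-processing statistics for
    large-eddy-simulation velocity-gradient exports (WALE eddy viscosity,
    energy dissipation rate, Kolmogorov length scale, shear stress,
    resolved-kinetic-energy ratio, surface-flux kL). Includes seeded synthetic
    generators for every input the pipeline consumes, with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
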