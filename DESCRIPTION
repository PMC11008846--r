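Package: pfnarel
Title: Probabilistic Failure Assessment of PFNA-Stabilized Intertrochanteric Fractures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reliability analysis of proximal femoral nail antirotation (PFNA)
    fixation of intertrochanteric fractures. A bivariate quadratic response
    surface approximates the peak compressive strain in the proximal trabecular
    bone as a function of apparent bone mineral density (BMD) and hip contact
    load (in body-weight multiples). Input uncertainty is propagated with a
    first-order second-moment (FOSM) method using closed-form moments of
    products and squares of independent normal variables, and the probability
    of failure (strain exceeding the compressive yield strain of trabecular
    bone) is obtained from the reliability index. Exact-moment and Monte Carlo
    modes are provided for verification, together with Latin hypercube
    sampling, a virtual-experiment generator for surrogate fitting, and
    scenario sweeps over age-group BMD and daily-activity loading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lhs,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
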