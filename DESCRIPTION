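Package: inhibkin
Title: Two-Site Enzyme Inhibition Kinetics and Mechanism Classification
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of enzyme initial-rate inhibition data
    under a general two-binding-site inhibitor model. The model places one
    inhibitor site inside the active site (dissociation constant gamma*Ki)
    and one beyond it (Ki), with a reactivity factor beta for the ternary
    complex, and reduces to the six classical intersecting inhibition
    mechanisms (linear/partial x competitive/non-competitive/mixed) in its
    limiting regimes. The package evaluates the general and traditional
    rate laws, maps parameters between the two descriptions, simulates
    assay designs, performs Lineweaver-Burk primary fits with secondary
    slope/intercept analysis and hyperbolic delta replots, classifies the
    inhibition mechanism, and estimates parameters via the classical
    reciprocal-space route or a direct global nonlinear fit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, minpack.lm
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
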