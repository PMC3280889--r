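Package: delayfield
Title: Stability Analysis of Neural Field Equations with Propagation Delays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for delayed neural field (Wilson-Cowan/Amari) equations on
    bounded domains, with space-dependent axonal propagation delays. Simulates
    the delayed integro-differential equations by a method-of-steps Runge-Kutta
    scheme with cubic Hermite history interpolation, locates stationary
    (persistent) states, and determines their linear stability three
    independent ways: characteristic roots of the per-mode characteristic
    equation on the homogeneous ring, eigenvalues of a Chebyshev-collocation
    discretization of the infinitesimal generator of the linearized delay
    semigroup, and two easy-to-evaluate sufficient stability bounds (one
    delay-independent, one depending on the maximal delay through a
    contraction constant). Traces pitchfork and Hopf bifurcation curves in
    the (delay scale, gain) plane, including the fold-Hopf point, and builds
    stability maps that compare the sufficient bounds with the exact spectral
    verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
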