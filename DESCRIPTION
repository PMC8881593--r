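Package: cxcompass
Title: Insect Central-Complex Ring-Attractor Model for Heading Estimation
    with Online Synaptic Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spiking implementation of the Drosophila central-complex
    heading-direction circuit: five leaky integrate-and-fire neuron
    populations (ring, E-PG, P-EN, P-EG, PIntr) wired with
    connectivity-constrained weights form a ring attractor whose activity
    bump tracks heading from angular-velocity input and visual landmark
    bearings.  The inhibitory ring-to-compass weight matrix is learned
    online with a presynaptically-gated Hebbian rule or an
    error-minimising rule derived from the same objective-function
    framework, and compared against an offline lasso-regularised
    non-negative regression optimum.  Includes synthetic environments and
    trajectories (rotation and translation), population-vector heading
    decoding, path integration, circular error metrics with bootstrap
    resampling, and a neuromorphic energy model for the full network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
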