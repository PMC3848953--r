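Package: mtupf
Title: Continuous-Time Particle Filtering Under Measurement-Time Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential Monte Carlo methods for continuous-time state-space
    models in which the times of the measurements are themselves random
    variables with known densities. Implements the measurement-time-uncertainty
    particle filter (MTU-PF), in which particle weights evolve by integrating
    partial-weight differential equations and the discretization stepsize
    adapts to the effective sample size, alongside the standard particle
    filter and a Kalman-filter maximum-likelihood baseline. Includes Bayesian
    parameter estimation via state augmentation with decaying artificial
    parameter dynamics, a four-compartment plasma-leucine tracer/tracee
    mixed-effects model with two patient groups, and synthetic-data
    generators for both applications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse,
    jsonlite
Config/testthat/edition: 3
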