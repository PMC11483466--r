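Package: ddfmpc
Title: Data-Driven Forecasting and Model Predictive Control of Conductance-Based Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Connor-Stevens (Hodgkin-Huxley type) neurons with Type-I
    or Type-II excitability, learns their voltage dynamics from current-clamp
    style recordings with a time-delay-embedded Gaussian radial basis function
    network trained by ridge regression, and uses the learned forecaster as the
    dynamics constraint of a receding-horizon nonlinear model predictive
    controller. Arbitrary reference voltage trajectories or spike trains can be
    imposed on the simulated neuron via bounded injected current, with only the
    membrane voltage observable. Includes chaotic (Lorenz-63) stimulus and
    Poisson/alpha-function synaptic noise generators, simplex-projection
    embedding-dimension selection, proportional-feedback, pulse and open-loop
    replay baseline controllers, and bivariate ISI- and SPIKE-distance spike
    train metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
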