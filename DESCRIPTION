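Package: netevents
Title: Network Events in Stochastic Neural Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of collective events in neural population
    activity. Implements a stochastic excitatory-inhibitory Wilson-Cowan rate
    model with a leaky integrate-and-fire transfer function, Tsodyks-Markram
    short-term synaptic depression, optional spike-frequency adaptation, and
    finite-size Poisson noise; linear stability analysis (fixed points,
    Jacobians, Hopf bifurcation maps) over the excitation-inhibition plane; a
    unified two-state hidden-Markov detector for network spikes, quasi-orbits
    and avalanches in binned spike counts; event-size statistics (Rayleigh /
    exponential quasi-orbit laws, exponential-plus-Gaussian mixture
    classification, power-law avalanche fits); and inference of the effective
    timescale of unobserved fatigue processes from firing history.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
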