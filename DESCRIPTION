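Package: spikeica
Title: Independent Component Learning in Stochastically Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a stochastically spiking neuron with refractoriness whose
    excitability is regulated by an intrinsic plasticity rule that drives the
    distribution of instantaneous firing rates towards an exponential with a
    fixed mean. Combined with nearest-neighbor spike-timing dependent
    plasticity (STDP) and multiplicative synaptic scaling, single neurons and
    laterally inhibited populations perform independent component analysis
    (ICA)-like learning on classic benchmarks: demixing rotated Laplacian
    sources (rate and spike encodings with on/off channels), Foldiak's bars
    problem in rate and spike-correlation encodings, and natural-image-like
    inputs. Includes the analytic BCM correspondence of nearest-neighbor STDP,
    correlated Poisson spike-train generation via dichotomous Gaussians, a
    rate-based reference model, and receptive-field analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
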