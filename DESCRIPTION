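Package: adexfit
Title: Multimodal Fitting of Adaptive Exponential Integrate-and-Fire Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits adaptive exponential integrate-and-fire (AdEx) point-neuron
    models to electrophysiological target features with a multimodal
    evolutionary optimizer. Provides a fast fixed-step AdEx simulator,
    extraction of spiking features (mean firing frequency, first-spike
    latency, per-cycle burst frequency under sinusoidal stimulation), a
    weighted multi-feature objective, the UEGO species-based multimodal
    optimizer with Solis-Wets (SASS) local search, synthetic reference
    generation, and post-hoc analysis of candidate populations (ranked
    score decomposition, classical multidimensional scaling, parameter
    quantile summaries). Developed around the cerebellar granule cell,
    whose theta-band spiking resonance motivates the burst-frequency
    feature, but applicable to any AdEx fitting task.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
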