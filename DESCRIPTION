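Package: anesnet
Title: Anesthetic Suppression and Cholinergic Reversal in Excitatory-Inhibitory Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biophysical (Hodgkin-Huxley) excitatory-inhibitory spiking network
    model of cortical anesthetic action and its reversal by muscarinic
    acetylcholine effects on the slow M-type potassium current. Provides a
    compiled network simulator with AMPA/NMDA/GABA-A synapses and lognormally
    distributed weights, spike-train measures (firing rates, mean phase
    coherence, information-theoretic integration and complexity),
    cross-correlogram functional-connectivity inference with jittered-surrogate
    null bands, a differential-evolution parameter fitter, synthetic spike-train
    generators for validation, and an orchestration layer that runs graded
    anesthesia and cholinergic-reversal parameter schedules and evaluates trend
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
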