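Package: stpbayes
Title: Bayesian Inference of Short-Term Synaptic Plasticity Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing short-term synaptic plasticity (STP)
    from trains of postsynaptic potential amplitudes. Implements the
    Tsodyks-Markram model family (depression-only, facilitation with f = U,
    and the extended four-parameter form) with an exact event-driven
    recursion, slice-sampling Markov chain Monte Carlo posterior inference
    of the dynamics parameters with analytic profiling of the amplitude
    factor, a simulated-annealing least-squares baseline, stimulation
    protocol generators and protocol quality scoring by sample estimation
    error, AIC-based model selection with Akaike weights, and
    posterior-distribution-based clustering (symmetrized Kullback-Leibler
    and Hellinger distances, average-linkage dendrograms, pseudo-F cluster
    number selection, dendrogram purity) plus Naive Bayes synapse-type
    classification with cross-validation. Includes generators of synthetic
    connection cohorts emulating neocortical excitatory connection classes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
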