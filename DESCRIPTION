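Package: spikeship
Title: Optimal-Transport Dissimilarity for Multi-Neuron Spiking Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes SpikeShip, a binless dissimilarity measure between
    multi-neuron spiking patterns based on optimal transport of spike mass.
    The transport cost between two epochs decomposes into a global temporal
    translation (the weighted median of all per-spike flows) and
    neuron-specific flows that carry all inter-neuronal relative spike-timing
    structure, so the measure is invariant to pattern latency and to firing
    rate scaling and has cost linear in neurons and spikes.  Includes
    inhomogeneous-Poisson pattern simulators, comparison measures
    (Victor-Purpura distance, z-scored firing-rate distance, a
    discriminability index), sliding-window epoching with silhouette-based
    window-length selection, clustering helpers, and a command-line
    interface over a long-format spike table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, cluster, mclust
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
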