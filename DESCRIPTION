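Package: neurocrit
Title: Mean-Field Thalamocortical Dynamics, Chaos Quantification, and
    Spectrally Resolved Transfer Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how proximity to edge-of-chaos criticality
    shapes cross-frequency communication between the cortex and thalamus.
    Provides a mean-field (neural mass) model of the nine-population basal
    ganglia-thalamo-cortical system with delayed damped-wave field
    propagation and geometric 'dose' interpolation between state-specific
    parameter sets; chaos quantification via twin-run stochastic largest
    Lyapunov exponents and the modified 0-1 chaos test; spectrally resolved
    directed information transfer combining Kraskov nearest-neighbour
    transfer entropy with maximal-overlap discrete wavelet transform band
    decomposition and iterative amplitude-adjusted Fourier transform
    band-restricted surrogates; trial preprocessing for paired extracellular
    field recordings; group-level statistics (exact signed-rank tests,
    harmonic-mean p-values, Modulation Index, Lempel-Ziv complexity,
    permutation ANCOVA); ground-truth synthetic benchmark generators; and a
    seeded genetic optimizer for state-specific model tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
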