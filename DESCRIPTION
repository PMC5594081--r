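Package: chronnect
Title: Chronnectomics of Dynamic EEG Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds integrated dynamic functional connectivity graphs (IDFCG)
    from multichannel EEG: sliding-window imaginary phase-locking value (iPLV)
    within eight frequency bands and across 28 phase-to-amplitude
    cross-frequency pairs, surrogate-based assignment of the dominant intrinsic
    coupling mode per sensor pair, data-driven topological filtering with
    orthogonal minimal spanning trees (OMST), non-negative matrix factorization
    plus neural-gas microstate symbolization of nodal global-efficiency time
    series, and a symbolic-dynamics feature set (transition rates, flexibility
    index, comodulograms, complexity index, Markov trajectory entropy, sample
    entropy) feeding support-vector age regression and extreme-learning-machine
    classification. Includes synthetic-data generators with planted coupling
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    e1071,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
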