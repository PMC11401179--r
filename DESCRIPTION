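Package: edgentropy
Title: Edge Sample Entropy Analysis of Time-Varying Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the timescales of time-varying functional
    connectivity (TVFC) in parcellated resting-state fMRI. Parcel timeseries
    are bandpass filtered, mean-signal regressed and windowed into edgewise
    correlation timeseries, whose regularity is quantified by sample entropy
    (edge sample entropy, ESE). High- and low-entropy network templates are
    built from group-mean ESE, and inter-subject similarity of masked ESE
    vectors enters a multivariate variance-component model of behavioral
    scores with moment-matching estimation, Wald and permutation inference,
    and bootstrap/jackknife contrasts. Includes system-block statistics
    under edge-shuffle and degree/strength-preserving rewiring nulls,
    normalized degree-centrality and node-entropy topography, spatially
    constrained surrogate tests for annotation-map correlations, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
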