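Package: hyperbrain
Title: Dual-EEG Hyperscanning Synchrony and Hyperbrain Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-electroencephalography (EEG)
    hyperscanning experiments with dyadic anti-phase tapping. Converts two
    participants' synchronized multichannel recordings into band-limited
    analytic-phase series, computes intra-brain synchrony with the weighted
    phase lag index (wPLI) and inter-brain synchrony with the phase locking
    value (PLV), thresholds every channel pair against Fourier
    phase-randomization surrogates to build a binary 58-node "hyperbrain"
    graph, and summarises its topology (edge number, global and local
    efficiency, fixed two-module modularity, path length, clustering).
    Behavioral coordination is quantified with inter-tap intervals and
    circular relative-phase statistics. A Kuramoto-style generator produces
    dual-EEG and tap fixtures with known ground-truth coupling so the whole
    pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
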