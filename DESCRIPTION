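Package: polychron
Title: Polychronous Spiking Network Memory with Programmable Axonal Delays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulator of a polychronous spiking neural network
    that stores spatio-temporal spike patterns in programmable axonal delays.
    Axon modules propagate spikes with per-path delays set either by one-shot
    delay programming or by spike-timing-dependent delay adaptation;
    coincidence-detector neurons (threshold 3-of-4 within a 1 ms window)
    regenerate a stored pattern from a four-spike cue. Includes LFSR-based
    pattern generation, Poisson noise injection, a recall checker, experiment
    harnesses for capacity, network-size and noise sweeps, and plain-text
    readers/writers for spike events and network snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
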