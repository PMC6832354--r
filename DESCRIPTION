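Package: eagdetect
Title: Odour-Response Detection in Noisy Electroantennogram Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting odour-evoked responses in single-channel
    electroantennogram (EAG) voltage recordings contaminated by baseline
    drift, power-line hum and broadband motor noise. Implements a
    conditional exponential moving average filter that enhances the
    negative response transients, a windowed dropping-counter (D-Counter)
    detector with a relative depth threshold, and a fixed-threshold
    baseline detector. Includes anti-aliased decimation, Welch power
    spectral density characterisation, maximum lagged cross-correlation
    scoring against the stimulus train, a four-variant comparison
    harness, and a seeded synthetic EAG generator emulating the four
    recording conditions (motor noise off/on crossed with odour
    absent/present), so the whole pipeline is testable without recorded
    data. A command-line interface exposes simulation, filtering,
    detection and benchmarking as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
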