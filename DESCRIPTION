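Package: chirpinvar
Title: Phase-Invariant Coding of Electrocommunication Chirps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying phase invariance of neural and
    behavioral responses to electrocommunication chirps in wave-type weakly
    electric fish. Synthesizes chirp-on-beat amplitude-modulation stimulus
    waveforms at the eight canonical beat-onset phases, simulates a model
    electrosensory hierarchy (P-unit afferents, ELL ON/OFF pyramidal cells,
    midbrain TS neurons) with seeded refractory-Poisson spiking, and computes
    spike-train statistics (PSTHs, time-varying across-trial spike-count
    correlation), log-ratio chirp responses, tuning curves, normalized
    response-distance metrics and phase-invariance scores, plus a behavioral
    echo-response pipeline (instantaneous EOD frequency from zero crossings,
    chirp event detection, echo rates and latencies, block-bootstrap standard
    errors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
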