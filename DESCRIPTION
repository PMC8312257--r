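Package: rcstream
Title: Ingestion, Time Reconstruction, and On-Device Power Emulation for
    Packetized Neural Telemetry Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with packetized multi-stream telemetry from
    implanted bidirectional neurostimulators that stream local field
    potentials, accelerometry, and on-board spectral features over a lossy
    transport. The package loads session folders of JSON documents (repairing
    truncated files), reconstructs a consistent per-sample unix time base for
    each stream despite packet loss, reordering, and disagreeing on-device
    clocks, harmonizes all streams onto one uniform time-domain grid with
    explicit missingness, and replicates the device's short-time FFT
    band-power engine off-device, including amplifier-calibration unit
    conversion, Hann window-load settings, and gain calibration. A built-in
    session simulator with retained ground truth provides an oracle for
    every processing stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    arrow,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
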