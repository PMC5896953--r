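Package: gcdspike
Title: Dendritic Spike Detection and Synaptic Plasticity Analysis for
    Granule Cell Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification chain for subcellular patch-clamp studies of
    hippocampal dentate gyrus granule cells: detection and classification
    of putative dendritic spikes from the temporal derivative of somatic
    voltage, backpropagating action-potential attenuation and conduction
    velocity analysis across soma-dendrite recording pairs, leak and
    capacitive current subtraction ('P over -4') with prepulse-based
    isolation of Na+, A-type K+ and delayed-rectifier K+ currents in
    outside-out patches, and theta-burst long-term potentiation
    quantification with induction spike-count association.  Includes a
    synthetic recording generator that emulates the signal structure of
    these experiments with full ground-truth logging, a plain-text session
    format, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
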