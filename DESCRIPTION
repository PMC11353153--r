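Package: fluopipe
Title: Calcium Imaging and Electrophysiology Co-Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable pipeline for two-photon calcium imaging movies
    recorded together with electrophysiology. Loads multipage TIFF frame- or
    line-scan movies and aligned field-potential recordings, detects somatic
    regions of interest on reference projections, validates them as cells and
    classifies each as astrocyte or neuron from two-channel fluorescence,
    extracts delta-F/F0 and delta-G/R traces with background correction,
    decomposes traces and ephys with a complex Morlet continuous wavelet
    transform into physiological frequency bands, quantifies pairwise network
    synchrony with phase-locking values and sliding-window cross-correlation,
    and renders per-cell and network HTML reports with batch processing over
    folders of saved sessions. Includes a ground-truth synthetic movie and
    ephys generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
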