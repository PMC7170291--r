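Package: sniqc
Title: Structured Noise Index Quality Control for Gamma-Camera Flood Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "physics-qc@example.org",
           role = c("aut", "cre"))
Description: Automated daily uniformity quality control for gamma cameras
    based on the structured noise index (SNI), a frequency-domain metric that
    separates structured (artifactual) noise from quantum (Poisson) noise in
    flood-field images. Implements the 2D noise power spectrum, quantum-noise
    subtraction, human visual response filtering, a roving-ROI sweep that
    scores the worst region of each flood, a Fourier-domain artifact image,
    and the traditional NEMA-style integral uniformity over UFOV/CFOV for
    comparison. Includes a minimal DICOM reader/writer for flood images, an
    analyze/alert/archive pipeline with two-level alerting, validation
    statistics (sensitivity against a service log, coefficient of variation),
    and a Poisson flood-field simulator with parameterized sensitivity
    defects (PMT dropout, gradients, sinusoids, edge bands) for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
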