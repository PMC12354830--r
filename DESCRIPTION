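Package: entofield
Title: Insect Monitoring from Electric-Field Sensor Recordings
Version: 0.1.0
Authors@R:
    person("FaunaField", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Signal-processing and statistics toolkit for automated insect
    monitoring with electrostatic field sensors. Turns raw one-minute,
    4 kHz sensor recordings into insect counts, wing-beat frequencies and
    biomass estimates: power-line interference detection (Welch PSD) and
    harmonic comb-filter cancellation, spectrogram-based convolutional
    neural network event detection, probabilistic-YIN wing-beat frequency
    estimation, Bhattacharyya-coefficient segment aggregation, and a
    region-structured wing-beat-frequency to body-mass lookup. Includes a
    ground-truth harmonic signal simulator for end-to-end testing and the
    paired-trap field-validation statistics (Spearman correlation, Fisher
    r-to-z comparison, ordinary least-squares slopes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
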