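Package: superspectra
Title: Consensus Biomarker Mass Fingerprints for MALDI-TOF Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds species-level consensus biomarker mass sets
    ("superspectra") from replicate MALDI-TOF peak lists, identifies
    unknown specimens against the resulting reference database by
    tolerance-matched biomarker fractions, gates spectra on data counts,
    computes Dice-coefficient distances with paired-group (UPGMA)
    dendrograms, and evaluates identification performance (sensitivity,
    specificity) from truth-versus-call ledgers. Includes peak-list
    readers for tabular and mzXML mass-list exports, cross-instrument
    harmonization of mass ranges and calibration offsets, and a seeded
    synthetic-data generator with storage-degradation and instrument
    effects for end-to-end testing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    ape,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
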