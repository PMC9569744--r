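Package: virtual2DE
Title: Virtual and Sectional Two-Dimensional Electrophoresis Maps from
    Peptide Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs quantitative two-dimensional electrophoresis
    (2DE) patterns of proteins and their proteoforms from per-section
    peptide identification tables, as produced by sectional analysis of a
    gel or by semi-virtual 2DE (isoelectric focusing followed by strip
    sectioning and LC-MS/MS).  Provides theoretical isoelectric point and
    molecular mass computation on the Bjellqvist pKa model with
    modification-aware charge accounting, in-silico tryptic digestion with
    the Keil rule, emPAI label-free quantification, calibration of pI and
    Mw axes, section-map construction, pattern comparison and vector
    rendering, and a seeded simulator of PTM-driven proteoform spot trains
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
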