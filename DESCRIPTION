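Package: flashERG
Title: Quantification of Full-Field Flash Electroretinograms with
    Oscillatory-Potential Isolation and Littermate-Normalized Group Statistics
Version: 0.1.0
Authors@R:
    person("ERG", "Tools", email = "erg.tools@example.org", role = c("aut", "cre"))
Description: Tools for analysing full-field flash electroretinogram (ERG)
    recordings from mice: sweep averaging with optional robust artifact
    rejection, zero-phase frequency-domain isolation of oscillatory
    potentials (OPs), a-wave and b-wave amplitude and implicit-time
    measurement, OP spectral amplitude in the 60-100 Hz band,
    normalization of mutant measures to wild-type littermate controls
    (percent-of-WT amplitudes, WT-subtracted implicit times), and the
    repeated-measures ANOVA decision tree (Mauchly sphericity,
    Greenhouse-Geisser / Huynh-Feldt corrections, Levene / Welch /
    Games-Howell for single-flash designs). Ships a seeded synthetic
    cohort generator with genotype presets for dystrophin-deficient mouse
    lines, calibrated against the package's own measurement operators so
    the whole pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
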