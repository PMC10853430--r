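Package: domforge
Title: Molecular Chemodiversity of Dissolved Organic Matter from
    FT-ICR-MS Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ultrahigh-resolution mass-spectrometry studies of
    soil dissolved organic matter (DOM).  Assigns CHNOS molecular formulas
    to FT-ICR-MS peak lists by exhaustive enumeration within a ppm
    tolerance, classifies formulas into the seven van Krevelen biochemical
    compound classes and the CHO/CHON/CHOS/CHONS element groups, summarises
    per-sample composition, partitions formulas between two conditions into
    degraded, remaining and produced sets, and infers signed Spearman
    co-occurrence networks linking DOM composition, soil chemistry and
    bacterial genera.  Includes a seeded synthetic-data generator that
    emulates a multi-year continuous-cropping soil study with known ground
    truth, so every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
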