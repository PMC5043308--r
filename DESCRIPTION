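Package: petoscan
Title: Metabolic-Rate-Aware Scans of Gene-Family Counts Against Body Mass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative genomic tests of the gene-abundance
    explanation of Peto's paradox. Scans per-species gene counts in
    functional categories (NOGF) against body mass, with and without
    correction for mass-specific metabolic rate via partial correlation
    and standardized partial regression, diagnoses metabolic-rate-driven
    spurious correlations through a correlation-of-correlations summary,
    tests enrichment of body-size-correlated categories in upper
    functional categories with Fisher's exact test, and verifies
    robustness with phylogenetically independent contrasts. Includes a
    KEGG BRITE flat-file counter, allometric (Kleiber) power-law fitting,
    and a synthetic-data generator emulating the allometric confound for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
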