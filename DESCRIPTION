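Package: lemurlife
Title: Life-History Table Derivation from Captive Strepsirrhine Colony Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives per-taxon life-history summary tables from longitudinal
    captive-colony studbook records for strepsirrhine primates (lemurs,
    lorises and galagos). Reads and validates the two record schemas used by
    the Duke Lemur Center colony archive (a per-individual animal list and a
    per-weighing weight file), and computes 91 summary variables per taxon:
    sample-size counts, reproduction (conception back-calculation from
    gestation, seasonal breeding-peak detection on monthly litter counts,
    litter-size statistics, parental ages at conception, birth sex ratio),
    longevity (censored product-limit survivorship and a distance-weighted
    median longevity, infant mortality), and body mass (neonate, young-adult
    and adult summaries with pre-death, pregnancy, wild-caught-juvenile and
    obesity exclusions). A synthetic-colony simulator with known demographic
    parameters generates schema-exact input files plus ground truth, so every
    derivation rule is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
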