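Package: spikeval
Title: Evaluation of Shotgun-Metagenomic Taxonomic Profiles Under Host DNA Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate taxonomic profiles of mock (spike-in) microbial
    communities as host DNA increasingly dominates a sample. Reads and writes
    Kraken 2 report and Bracken species-output tables, maintains a lightweight
    taxonomy for lineage queries, estimates genome-size-normalized relative
    abundances and scores them against theoretical community composition
    (detection, observed/expected ratio bands, mean squared relative error,
    GC association), classifies off-target genera as synthetic- or
    host-associated from a dilution series, and identifies constant-mass
    contaminants with a frequency-based test that uses total microbial read
    counts as the DNA-concentration proxy. A taxon-level simulator of the
    underlying spike-in experiment (staggered 20-species community, host
    dilution series, co-varying contaminants, classifier misassignment)
    makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
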