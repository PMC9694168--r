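Package: aapred
Title: Ligand-Based Prediction of Antiproliferative Activity Across
    Cancer Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts -logGI50 (pGI50) growth-inhibition profiles of small
    molecules against a panel of tumor cell lines from molecular
    descriptors alone.  Two complementary scorers are combined: a
    descriptor-tolerance similarity module that transfers the experimental
    activities of the closest training compound, and a per-cell-line
    template module that bins training activities into 42 narrow pGI50
    intervals, summarizes each bin by per-descriptor mean and standard
    deviation, and assigns a query the activity of its best-matching bin.
    Includes readers for SDF/SMILES structures and delimited activity
    tables, a pluggable descriptor backend (a 2D backend built on
    ChemmineR is shipped), absolute-deviation validation reports, a
    parameter-tuning grid, model serialization, and a synthetic-data
    generator with planted bin structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
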