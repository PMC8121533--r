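Package: scmetaudit
Title: Audit Cell-Level Metadata Deposition in Public Single-Cell Repositories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for auditing how often public single-cell RNA-seq
    depositions include cell-level metadata (cell type or cluster
    assignments, embedding coordinates) alongside the count matrix.
    Parses cached GEO series records (SOFT, DocSum and tabular dialects)
    and ArrayExpress IDF/SDRF documents, merges SuperSeries families,
    classifies supplementary file names with a substring/extension rule
    set, corrects the raw detection rate with manual spot-check error
    rates (precision and miss rate), stratifies prevalence by year,
    journal group and tool-author status, validates count-matrix and
    metadata concordance of individual deposits, and generates synthetic
    record corpora with planted ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
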