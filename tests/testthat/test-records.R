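test_that("SOFT blocks parse into records with basenames only", {
  soft <- c(
    "!Series_geo_accession = GSE137710",
    "!Series_title = Melanoma and spleen single cell RNA-seq",
    "!Series_submission_date = Sep 18 2019",
    "!Series_pubmed_id = 31588021",
    paste0("!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/geo/",
           "series/GSE137nnn/GSE137710/suppl/",
           "GSE137710_human_melanoma_cell_metadata_9315x14.tsv.gz")
  )
  rec <- parse_record(soft, dialect = "soft")
  expect_equal(rec$accession, "GSE137710")
  expect_equal(rec$supp_series,
               "GSE137710_human_melanoma_cell_metadata_9315x14.tsv.gz")
  expect_equal(rec$record_type, "series")
  expect_equal(rec$submission_date, as.Date("2019-09-18"))
  expect_equal(rec$publication_id, "31588021")
})

test_that("records without supplementary lines get empty filename lists", {
  rec <- parse_record(c("!Series_geo_accession = GSE1",
                        "!Series_title = something"), dialect = "soft")
  expect_length(rec$supp_series, 0)
  expect_length(rec$supp_sample, 0)
})

test_that("relations set the record type and related accessions", {
  sup <- parse_record(c("!Series_geo_accession = GSE2",
                        "!Series_relation = SuperSeries of: GSE3",
                        "!Series_relation = SuperSeries of: GSE4"), "soft")
  expect_equal(sup$record_type, "superseries")
  expect_setequal(sup$related_accessions, c("GSE3", "GSE4"))
  sub <- parse_record(c("!Series_geo_accession = GSE3",
                        "!Series_relation = SubSeries of: GSE2"), "soft")
  expect_equal(sub$record_type, "subseries")
  expect_equal(sub$related_accessions, "GSE2")
})

test_that("malformed records fail with named dialect", {
  expect_error(parse_record("", "soft"), "empty input")
  expect_error(parse_record("!Series_title = no accession here", "soft"),
               "accession")
  expect_error(parse_record("<DocSum><Item Name='title'>x</Item></DocSum>",
                            "docsum"), "Accession")
  expect_error(parse_record("\ttitle only, empty accession", "tabular"),
               "accession")
})

test_that("docsum XML parses accession, files, date and pubmed id", {
  doc <- load_corpus(extdata("geo_docsum.xml"))
  expect_equal(doc$accession, c("GSE900010", "GSE900011"))
  expect_equal(doc$supp_series[[1]],
               c("GSE900010_retina_metadata.tsv.gz", "GSE900010_counts.mtx.gz"))
  expect_equal(doc$publication_id, c("32555229", NA))
  expect_equal(doc$submission_date[[1]], as.Date("2020-07-21"))
})

test_that("parsing is deterministic", {
  soft <- c("!Series_geo_accession = GSE9",
            "!Series_supplementary_file = a_meta.tsv.gz")
  expect_identical(parse_record(soft, "soft"), parse_record(soft, "soft"))
})

test_that("duplicate accessions collapse to the first with a warning", {
  recs <- list(repo_record("GSE1", title = "first"),
               repo_record("GSE1", title = "second"),
               repo_record("GSE2"))
  expect_warning(corp <- record_corpus(recs), "duplicate")
  expect_equal(nrow(corp), 2)
  expect_equal(corp$title[corp$accession == "GSE1"], "first")
})

test_that("a corpus round-trips through the tabular dialect unchanged", {
  corp <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  back <- load_corpus(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(corp))
  expect_equal(attr(back, "snapshot_date"), attr(corp, "snapshot_date"))
  expect_equal(attr(back, "corpus_source"), attr(corp, "corpus_source"))
})

test_that("loading a missing or recordless file errors", {
  expect_error(load_corpus(file.path(tempdir(), "nope.tsv")), "no such file")
  empty <- withr::local_tempfile(fileext = ".soft")
  writeLines("# nothing here", empty)
  expect_error(load_corpus(empty), "empty corpus")
})

test_that("the SOFT fixture loads all five series", {
  corp <- load_corpus(extdata("geo_series.soft"))
  expect_equal(nrow(corp), 5)
  expect_equal(sum(corp$record_type == "superseries"), 1)
  expect_equal(sum(corp$record_type == "subseries"), 2)
  # sample-level file landed in the sample pool, not the series pool
  expect_equal(corp$supp_sample[[which(corp$accession == "GSE900003")]],
               "GSM1000001_barcodes.tsv.gz")
})
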