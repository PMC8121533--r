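test_that("worked filename examples classify as expected", {
  m <- classify_filename("GSE137710_human_melanoma_cell_metadata_9315x14.tsv.gz")
  expect_true("meta" %in% m$rule)
  expect_equal(nrow(classify_filename("raw_data_10x.txt")), 0)
  expect_true("meta" %in% classify_filename("meta_10x.txt")$rule)
  obj <- classify_filename("seurat_object.rds")
  expect_equal(obj$rule, "rds")
  expect_equal(obj$rule_kind, "extension")
  # documented false-positive mode: "type" inside "genotype"
  expect_true("type" %in% classify_filename("genotype_calls.vcf.gz")$rule)
})

test_that("extension rules strip one compression suffix and .rdata matches both tokens", {
  expect_equal(classify_filename("obj.h5ad.gz")$rule, "h5ad")
  expect_equal(nrow(classify_filename("archive.rds.tar")), 0)
  rdata <- classify_filename("session.RData")
  expect_setequal(rdata$rule, c("rda", "rdata"))
  # substrings of the name are not extensions
  expect_equal(nrow(classify_filename("lo_omics.txt")), 0)
  expect_equal(nrow(classify_filename("discards.txt")), 0)
})

test_that("substring extension mode widens matches (sensitivity toggle)", {
  rules <- suppressMessages(pattern_rules(extension_mode = "substring"))
  expect_true("rds" %in% classify_filename("rds_export_notes.txt", rules)$rule)
})

test_that("empty names violate the classifier contract", {
  expect_error(classify_filename(""), "nonempty")
})

test_that("record verdicts respect scope and union semantics", {
  neutral <- repo_record("GSE1", supp_series = c("matrix.mtx.gz",
                                                 "barcodes.tsv.gz",
                                                 "features.tsv.gz"))
  expect_false(classify_record(neutral)$positive)
  pos <- repo_record("GSE2", supp_series = c("counts.csv", "cell_annotations.csv"))
  v <- classify_record(pos)
  expect_true(v$positive)
  expect_equal(v$matched$rule, "annot")
  # metadata file only attached at sample level: invisible in mirror scope
  sample_only <- repo_record("GSE3", supp_series = "counts.csv",
                             supp_sample = "meta.tsv.gz")
  expect_false(classify_record(sample_only, scope = "series_level")$positive)
  expect_true(classify_record(sample_only, scope = "all_levels")$positive)
  # no files at all -> negative, not an error
  expect_false(classify_record(repo_record("GSE4"))$positive)
})

test_that("a merged family is positive when only a subseries held the metadata file", {
  merged <- suppressMessages(merge_superseries(tiny_corpus()))
  v <- classify_corpus(merged)
  expect_true(v$positive[v$accession == "GSE2"])
})

test_that("classifier equals the brute-force character-scan oracle on the synthetic vocabulary", {
  rules <- pattern_rules()
  for (name in synthetic_vocabulary()) {
    expect_equal(nrow(classify_filename(name, rules)) > 0,
                 oracle_classify(name, rules),
                 info = name)
  }
})

test_that("classification is invariant under filename case changes (property)", {
  set.seed(7)
  vocab <- synthetic_vocabulary()
  for (i in seq_len(50)) {
    name <- sample(vocab, 1)
    ch <- strsplit(name, "")[[1]]
    flip <- runif(length(ch)) < 0.5
    ch[flip] <- toupper(ch[flip])
    scrambled <- paste(ch, collapse = "")
    expect_equal(classify_filename(scrambled)$rule, classify_filename(name)$rule,
                 info = scrambled)
  }
})

test_that("adding a filename never flips a positive verdict to negative (monotonicity)", {
  set.seed(11)
  vocab <- synthetic_vocabulary()
  for (i in seq_len(30)) {
    files <- sample(vocab, sample(1:4, 1))
    rec <- repo_record("GSEX", supp_series = files)
    extended <- repo_record("GSEX", supp_series = c(files, sample(vocab, 1)))
    if (classify_record(rec)$positive) {
      expect_true(classify_record(extended)$positive)
    }
  }
})

test_that("detected_fraction counts planted positives exactly", {
  recs <- c(
    lapply(1:50, function(i) repo_record(sprintf("P%03d", i),
                                         supp_series = "cell_metadata.tsv.gz")),
    lapply(1:150, function(i) repo_record(sprintf("N%03d", i),
                                          supp_series = "matrix.mtx.gz"))
  )
  corp <- record_corpus(recs, source = "synthetic")
  d <- detected_fraction(corp)
  expect_equal(d$n_positive, 50)
  expect_equal(d$n_records, 200)
  expect_equal(d$percent, 25.0)
})

test_that("detected_fraction hits the degenerate bounds and guards its contract", {
  none <- record_corpus(lapply(1:4, function(i) {
    repo_record(paste0("Z", i), supp_series = "matrix.mtx.gz")
  }))
  expect_equal(detected_fraction(none)$percent, 0.0)
  all_pos <- record_corpus(lapply(1:4, function(i) {
    repo_record(paste0("A", i), supp_series = "object.rds")
  }))
  expect_equal(detected_fraction(all_pos)$percent, 100.0)
  expect_error(detected_fraction(tiny_corpus()), "subseries")
})
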