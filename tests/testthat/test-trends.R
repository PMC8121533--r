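pub_fixture <- function() {
  tibble::tibble(
    publication_id = c("31588021", "32433969"),
    year = c(2019L, 2020L),
    journal = c("Journal of broad science 1", "Journal of field science 2"),
    citation_count = c(40L, 12L),
    has_tool_author = c(TRUE, FALSE)
  )
}

annotated_fixture <- function() {
  merged <- suppressMessages(merge_superseries(tiny_corpus()))
  list(annotated = suppressMessages(join_publications(merged, pub_fixture())),
       verdicts = classify_corpus(merged))
}

test_that("publication join annotates matches and flags the rest", {
  fx <- annotated_fixture()
  ann <- fx$annotated
  expect_equal(sum(ann$annotated), 2)
  expect_equal(sum(!ann$annotated), 1)
  expect_equal(ann$audit_year[ann$accession == "GSE1"], 2019)
  # unlinked record falls back to its submission year
  expect_equal(ann$audit_year[ann$accession == "GSE5"], 2018)
  expect_error(
    join_publications(suppressMessages(merge_superseries(tiny_corpus())),
                      dplyr::bind_rows(pub_fixture(), pub_fixture())),
    "duplicate")
})

test_that("per-year fractions count directly and come back in ascending order", {
  fx <- annotated_fixture()
  by_year <- fraction_by_year(fx$annotated, fx$verdicts)
  expect_equal(by_year$stratum_label, c(2019L, 2020L))
  expect_equal(by_year$n_records, c(1L, 1L))
  expect_equal(by_year$n_positive, c(1L, 1L))
  expect_equal(by_year$fraction, c(1, 1))
})

test_that("missing verdicts are contract errors naming the accession", {
  fx <- annotated_fixture()
  v <- fx$verdicts[fx$verdicts$accession != "GSE1", ]
  expect_error(fraction_by_year(fx$annotated, v), "GSE1")
})

test_that("journal groups partition annotated records with an 'other' catch-all", {
  fx <- annotated_fixture()
  by_group <- fraction_by_group(fx$annotated, fx$verdicts,
                                c("Journal of broad science 1" = "broad"))
  expect_setequal(by_group$stratum_label, c("broad", "other"))
  expect_equal(sum(by_group$n_records), sum(fx$annotated$annotated))
  expect_equal(sum(by_group$share_of_total), 1)
  all_other <- fraction_by_group(fx$annotated, fx$verdicts, character())
  expect_equal(all_other$stratum_label, "other")
})

test_that("citation comparison returns per-arm medians with missing markers", {
  fx <- annotated_fixture()
  cc <- citation_comparison(fx$annotated, fx$verdicts, years = c(2019, 2013))
  pos2019 <- cc[cc$year == 2019 & cc$metadata, ]
  expect_equal(pos2019$n, 1)
  expect_equal(pos2019$median_citations, 40)
  empty <- cc[cc$year == 2013, ]
  expect_true(all(is.na(empty$median_citations)))
  expect_true(all(empty$n == 0))
})

test_that("tool-author split separates the two strata from since_year onward", {
  fx <- annotated_fixture()
  ta <- tool_author_split(fx$annotated, fx$verdicts, since_year = 2017)
  expect_setequal(ta$stratum_label, c("tool_author", "other"))
  expect_equal(ta$n_records[ta$stratum_label == "tool_author"], 1L)
  beyond <- tool_author_split(fx$annotated, fx$verdicts, since_year = 2050)
  expect_equal(beyond$n_records, c(0L, 0L))
})

test_that("planted stratification structure is recovered on a synthetic corpus", {
  spec <- corpus_spec(
    n_records = 1200,
    contamination_other_modality = 0,
    superseries_rate = 0,
    prevalence_by_year = c("2014" = 0.10, "2015" = 0.125, "2016" = 0.15,
                           "2017" = 0.175, "2018" = 0.2, "2019" = 0.225,
                           "2020" = 0.25),
    tool_author_rate = 0.3,
    tool_author_prevalence_boost = 2,
    publication_link_rate = 1,
    seed = 20240
  )
  gen <- generate_corpus(spec)
  corpus <- gen$corpus
  verdicts <- classify_corpus(corpus)
  annotated <- join_publications(corpus, gen$pubs)

  by_year <- fraction_by_year(annotated, verdicts)
  # partition property and planted upward trend (late years above early ones)
  expect_equal(sum(by_year$n_records), nrow(corpus))
  early <- sum(by_year$n_positive[by_year$stratum_label <= 2016]) /
    sum(by_year$n_records[by_year$stratum_label <= 2016])
  late <- sum(by_year$n_positive[by_year$stratum_label >= 2019]) /
    sum(by_year$n_records[by_year$stratum_label >= 2019])
  expect_gt(late, early)

  grouping <- utils::read.delim(extdata("journal_groups.tsv"))
  by_group <- fraction_by_group(annotated, verdicts, grouping)
  expect_equal(sum(by_group$n_records), nrow(corpus))
  expect_true(all(by_group$fraction >= 0 & by_group$fraction <= 1))

  ta <- tool_author_split(annotated, verdicts, since_year = 2017)
  expect_equal(sum(ta$n_records),
               sum(annotated$audit_year >= 2017))
  expect_gt(ta$fraction[ta$stratum_label == "tool_author"],
            ta$fraction[ta$stratum_label == "other"])

  cc <- citation_comparison(annotated, verdicts, years = 2017)
  expect_gt(cc$median_citations[cc$metadata],
            cc$median_citations[!cc$metadata])
})

test_that("stratified summaries are invariant under record order (property)", {
  fx <- annotated_fixture()
  perm <- sample(nrow(fx$annotated))
  shuffled <- fx$annotated[perm, ]
  expect_equal(fraction_by_year(shuffled, fx$verdicts),
               fraction_by_year(fx$annotated, fx$verdicts))
  expect_equal(
    fraction_by_group(shuffled, fx$verdicts, c("Journal of broad science 1" = "broad")),
    fraction_by_group(fx$annotated, fx$verdicts, c("Journal of broad science 1" = "broad")))
})
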