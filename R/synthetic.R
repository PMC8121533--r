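#' Specification for a synthetic record corpus
#'
#' Describes a corpus of repository records with planted ground truth, so
#' the harvest, classifier, validation and trend stages can be exercised and
#' checked offline. The defaults emulate the rates a keyword-harvested GEO
#' single-cell corpus exhibits: roughly one in ten keyword hits is another
#' sequencing modality, under a fifth of true single-cell studies deposit
#' cell-level metadata, a third of deposited metadata files carry names the
#' filename rules cannot see, and a small fraction of metadata-free records
#' carry decoy names (gene-annotation files, genotype tables, generic R
#' objects) that the rules wrongly flag.
#'
#' @param n_records Number of (post-merge) study records.
#' @param prevalence_metadata Probability a true single-cell record truly
#'   deposits cell-level metadata.
#' @param contamination_other_modality Probability a record is a
#'   keyword-matching non-single-cell study (e.g. bulk RNA-seq).
#' @param metadata_miss_rate Probability a truly deposited metadata file has
#'   a name the rules miss (e.g. `cluster_ids.csv`, `cell_info.txt`).
#' @param classifier_fp_vocab_rate Probability a record without cell-level
#'   metadata carries a decoy filename that triggers the rules anyway.
#' @param celltype_given_metadata Probability a deposited metadata table
#'   names actual cell types rather than bare cluster labels.
#' @param superseries_rate Probability a study is deposited as a SuperSeries
#'   family of 2-4 subseries instead of a single series.
#' @param year_range Two-element integer vector of publication years.
#' @param prevalence_by_year Optional named numeric vector overriding
#'   `prevalence_metadata` per year (names = years); used to plant a
#'   temporal trend.
#' @param publication_link_rate Probability a record has a linked PubMed
#'   identifier (and hence publication info).
#' @param tool_author_rate Probability a publication has an author who
#'   previously published a single-cell software tool.
#' @param tool_author_prevalence_boost Multiplier on the metadata prevalence
#'   for tool-author records (capped at 1).
#' @param citation_meanlog_positive,citation_meanlog_negative,citation_sdlog
#'   Log-normal citation-count model per verdict arm (heavy-tailed, as
#'   observed citation distributions are).
#' @param journal_groups Character vector of journal-group labels records
#'   are assigned to uniformly.
#' @param seed Integer seed; the same spec always generates the same corpus.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 500,
                        prevalence_metadata = 0.187,
                        contamination_other_modality = 0.098,
                        metadata_miss_rate = 0.35,
                        classifier_fp_vocab_rate = 0.02,
                        celltype_given_metadata = 0.9,
                        superseries_rate = 0.1,
                        year_range = c(2014L, 2020L),
                        prevalence_by_year = NULL,
                        publication_link_rate = 0.8,
                        tool_author_rate = 0.1,
                        tool_author_prevalence_boost = 2,
                        citation_meanlog_positive = 2.8,
                        citation_meanlog_negative = 2.5,
                        citation_sdlog = 1,
                        journal_groups = c("broad", "field", "specialist"),
                        seed = 1L) {
  probs <- c(prevalence_metadata, contamination_other_modality,
             metadata_miss_rate, classifier_fp_vocab_rate,
             celltype_given_metadata, superseries_rate,
             publication_link_rate, tool_author_rate)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("corpus_spec: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(prevalence_by_year) &&
      (anyNA(prevalence_by_year) || any(prevalence_by_year < 0) ||
       any(prevalence_by_year > 1))) {
    stop("corpus_spec: prevalence_by_year values must lie in [0, 1]",
         call. = FALSE)
  }
  if (length(n_records) != 1 || is.na(n_records) || n_records < 1) {
    stop("corpus_spec: n_records must be a positive count", call. = FALSE)
  }
  structure(mget(names(formals())), class = "corpus_spec")
}

# filename vocabularies ------------------------------------------------------

synth_metadata_vocab <- function() {
  c("%s_cell_metadata.tsv.gz", "%s_metadata.csv.gz", "cell_annotations.csv",
    "%s_cell_type_assignments.tsv.gz", "clustering_results.tsv.gz",
    "%s_coldata.tsv.gz", "seurat_object.rds", "%s_processed.h5ad",
    "analysis.rda", "%s_counts.loom", "meta_10x.txt")
}

# metadata files whose names the substring/extension rules cannot see
synth_missed_vocab <- function() {
  c("%s_cell_info.tsv.gz", "cluster_ids.csv", "%s_cell_labels.txt.gz",
    "per_cell_table.tsv", "%s_umap.tsv.gz")
}

# classifier decoys: gene annotations, genotype tables, non-single-cell
# R objects — the documented false-positive modes
synth_decoy_vocab <- function() {
  c("gene_annotation.gtf.gz", "genotype_calls.vcf.gz",
    "%s_isotype_controls.csv", "probe_annotations.txt.gz",
    "network_object.rda", "bulk_counts_annotated.tsv.gz")
}

synth_neutral_vocab <- function() {
  c("matrix.mtx.gz", "barcodes.tsv.gz", "features.tsv.gz",
    "%s_raw_counts.tsv.gz", "raw_data_10x.txt", "%s_fpkm.txt.gz",
    "filtered_feature_bc_matrix.tar.gz")
}

fill_acc <- function(template, acc) {
  ifelse(grepl("%s", template, fixed = TRUE),
         vapply(template, function(t) {
           if (grepl("%s", t, fixed = TRUE)) sprintf(t, acc) else t
         }, character(1), USE.NAMES = FALSE),
         template)
}

synth_sc_titles <- function() {
  c("Single cell RNA-seq of %s",
    "scRNA-seq atlas of %s",
    "snRNA-seq profiling of %s",
    "Single nuclei transcriptomics of %s",
    "Droplet scRNAseq survey of %s")
}

synth_bulk_titles <- function() {
  c("Bulk RNA-seq of %s with single cell resolution claims",
    "RNA profiling of sorted single cell populations from %s",
    "ATAC-seq and single cell comparisons in %s")
}

synth_tissues <- function() {
  c("mouse cortex", "human melanoma", "zebrafish retina", "human PBMC",
    "mouse intestinal crypt", "human fetal liver", "drosophila embryo")
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Draws one record per study under the rates in the spec, assembles
#' parseable repository records (a fraction deposited as SuperSeries
#' families whose files are spread over subseries), and returns the pre-merge
#' corpus together with a per-study ground-truth table. Filenames are drawn
#' from four vocabularies: rule-matching metadata names, metadata names the
#' rules miss, decoy names that wrongly trigger the rules, and neutral
#' matrix/raw-data names every record carries.
#'
#' @param spec A [corpus_spec()].
#' @return A list with elements `corpus` (a [record_corpus()], source
#'   `"synthetic"`, including subseries rows when families were planted),
#'   `truth` (tibble: `accession`, `is_single_cell`, `has_metadata`,
#'   `has_cell_type`, `year`, `journal_group`, `has_tool_author`,
#'   `citation_count`, `publication_id`) and `pubs` (a publication-info
#'   table for [join_publications()]).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  n <- as.integer(spec$n_records)
  years <- seq(spec$year_range[1], spec$year_range[2])
  acc <- sprintf("SYN%06d", seq_len(n))
  year <- sample(years, n, replace = TRUE)
  is_sc <- stats::runif(n) >= spec$contamination_other_modality
  tool <- stats::runif(n) < spec$tool_author_rate

  prev <- rep(spec$prevalence_metadata, n)
  if (!is.null(spec$prevalence_by_year)) {
    hit <- as.character(year) %in% names(spec$prevalence_by_year)
    prev[hit] <- spec$prevalence_by_year[as.character(year[hit])]
  }
  prev <- pmin(1, prev * ifelse(tool, spec$tool_author_prevalence_boost, 1))
  has_meta <- is_sc & stats::runif(n) < prev
  has_celltype <- has_meta & stats::runif(n) < spec$celltype_given_metadata
  meta_missed <- has_meta & stats::runif(n) < spec$metadata_miss_rate
  decoy <- !has_meta & stats::runif(n) < spec$classifier_fp_vocab_rate

  has_pub <- stats::runif(n) < spec$publication_link_rate
  pmid <- ifelse(has_pub, sprintf("3%07d", seq_len(n)), NA_character_)
  journal_group <- sample(spec$journal_groups, n, replace = TRUE)
  journal <- paste0("Journal of ", journal_group, " science ",
                    sample(1:3, n, replace = TRUE))
  # classifier-visible metadata raises citations (the planted Fig-2C effect)
  meanlog <- ifelse(has_meta & !meta_missed,
                    spec$citation_meanlog_positive,
                    spec$citation_meanlog_negative)
  citations <- as.integer(round(stats::rlnorm(n, meanlog, spec$citation_sdlog)))

  tissues <- sample(synth_tissues(), n, replace = TRUE)
  title <- vapply(seq_len(n), function(i) {
    pool <- if (is_sc[i]) synth_sc_titles() else synth_bulk_titles()
    sprintf(sample(pool, 1), tissues[i])
  }, character(1))

  files <- lapply(seq_len(n), function(i) {
    f <- fill_acc(sample(synth_neutral_vocab(), 2), acc[i])
    if (has_meta[i]) {
      pool <- if (meta_missed[i]) synth_missed_vocab() else synth_metadata_vocab()
      f <- c(f, fill_acc(sample(pool, 1), acc[i]))
    }
    if (decoy[i]) f <- c(f, fill_acc(sample(synth_decoy_vocab(), 1), acc[i]))
    unique(f)
  })

  is_family <- stats::runif(n) < spec$superseries_rate
  sub_counter <- 0L
  records <- vector("list", 0L)
  for (i in seq_len(n)) {
    sdate <- as.Date(sprintf("%d-06-15", year[i]))
    common <- list(
      title = title[i],
      summary = sprintf("We profiled %s.%s", tissues[i],
                        if (is_sc[i]) " Single cell transcriptomes were measured." else ""),
      overall_design = if (is_sc[i]) "single cell RNA sequencing" else "bulk RNA sequencing",
      submission_date = sdate,
      publication_id = pmid[i],
      library_strategy_text = "Expression profiling by high throughput sequencing"
    )
    if (!is_family[i]) {
      records[[length(records) + 1L]] <- do.call(repo_record, c(
        list(accession = acc[i], record_type = "series",
             supp_series = files[[i]]), common))
    } else {
      k <- sample(2:4, 1)
      subs <- sprintf("%sS%d", acc[i], seq_len(k))
      sub_counter <- sub_counter + k
      assign_to <- sample(k, length(files[[i]]), replace = TRUE)
      records[[length(records) + 1L]] <- do.call(repo_record, c(
        list(accession = acc[i], record_type = "superseries",
             related_accessions = subs, supp_series = character()), common))
      for (j in seq_len(k)) {
        sub_common <- common
        sub_common$publication_id <- NA_character_
        sub_common$submission_date <- sdate + j
        records[[length(records) + 1L]] <- do.call(repo_record, c(
          list(accession = subs[j], record_type = "subseries",
               related_accessions = acc[i],
               supp_series = files[[i]][assign_to == j]), sub_common))
      }
    }
  }

  truth <- tibble::tibble(
    accession = acc,
    is_single_cell = is_sc,
    has_metadata = has_meta,
    has_cell_type = has_celltype,
    metadata_name_missed = meta_missed,
    decoy_present = decoy,
    year = as.integer(year),
    journal = journal,
    journal_group = journal_group,
    has_tool_author = tool,
    citation_count = citations,
    publication_id = pmid
  )
  pubs <- truth[!is.na(truth$publication_id),
                c("publication_id", "year", "journal", "citation_count",
                  "has_tool_author")]
  list(
    corpus = record_corpus(records, snapshot_date = as.Date("2020-12-31"),
                           source = "synthetic"),
    truth = truth,
    pubs = pubs
  )
}

#' Simulate a manual spot check against planted ground truth
#'
#' Samples records uniformly without replacement from a merged corpus,
#' classifies them, and tallies the same contingency quantities a manual
#' inspection would: single-cell or another modality, called positive or
#' negative, truly carrying metadata or not.
#'
#' @param corpus A merged `record_corpus` (run [merge_superseries()] first).
#' @param truth The ground-truth table from [generate_corpus()].
#' @param n_inspected Sample size (<= corpus size); inspecting the whole
#'   corpus yields the exhaustive census tallies.
#' @param seed Integer seed for the sampling step.
#' @param rules,scope Passed to [classify_corpus()].
#' @return A [validation_counts()] object.
#' @export
simulate_spot_check <- function(corpus, truth, n_inspected, seed = 1L,
                                rules = pattern_rules(),
                                scope = c("series_level", "all_levels")) {
  scope <- match.arg(scope)
  stopifnot(inherits(corpus, "record_corpus"))
  if (n_inspected > nrow(corpus)) {
    stop("n_inspected exceeds corpus size", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  pick <- sort(sample(nrow(corpus), n_inspected))
  sub <- new_record_corpus(tibble::as_tibble(corpus)[pick, , drop = FALSE],
                           snapshot_date = attr(corpus, "snapshot_date"),
                           source = attr(corpus, "corpus_source"))
  verdicts <- classify_corpus(sub, rules = rules, scope = scope)
  tt <- dplyr::left_join(verdicts, truth, by = "accession")
  if (anyNA(tt$is_single_cell)) {
    stop("ground truth missing for inspected record(s)", call. = FALSE)
  }
  sc <- tt[tt$is_single_cell, , drop = FALSE]
  called_pos <- sc$positive
  validation_counts(
    n_inspected = nrow(tt),
    n_true_single_cell = nrow(sc),
    n_called_positive = sum(called_pos),
    n_true_positive = sum(called_pos & sc$has_metadata),
    n_missed_with_metadata = sum(!called_pos & sc$has_metadata),
    n_with_cell_type = sum(called_pos & sc$has_metadata & sc$has_cell_type)
  )
}
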