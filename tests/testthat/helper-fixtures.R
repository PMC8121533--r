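# shared fixtures and independent oracles

extdata <- function(...) system.file("extdata", ..., package = "scmetaudit")

# a tiny hand-built corpus: one plain series with a metadata file, one
# superseries family whose metadata file sits in a subseries, one bulk study
tiny_corpus <- function() {
  record_corpus(list(
    repo_record("GSE1", title = "Single cell RNA-seq of melanoma",
                summary = "droplet scRNA-seq",
                supp_series = c("GSE1_cell_metadata.tsv.gz", "GSE1_counts.tsv.gz"),
                submission_date = as.Date("2019-09-18"),
                publication_id = "31588021"),
    repo_record("GSE2", title = "Cortex single nuclei SuperSeries",
                summary = "snRNA-seq of cortex",
                record_type = "superseries",
                related_accessions = c("GSE3", "GSE4"),
                submission_date = as.Date("2020-03-02")),
    repo_record("GSE3", title = "Cortex batch 1", summary = "snRNAseq",
                record_type = "subseries", related_accessions = "GSE2",
                supp_series = "matrix.mtx.gz",
                supp_sample = "GSM1_barcodes.tsv.gz",
                submission_date = as.Date("2020-03-03"),
                publication_id = "32433969"),
    repo_record("GSE4", title = "Cortex batch 2", summary = "snRNAseq",
                record_type = "subseries", related_accessions = "GSE2",
                supp_series = "cell_annotations.tsv.gz",
                submission_date = as.Date("2020-03-04")),
    repo_record("GSE5", title = "Bulk RNA-seq of sorted populations",
                summary = "bulk profiling",
                supp_series = "GSE5_fpkm.txt.gz",
                submission_date = as.Date("2018-01-10"))
  ), snapshot_date = as.Date("2020-12-31"), source = "geo")
}

all_corpus_filenames <- function(corpus) {
  sort(c(unlist(corpus$supp_series), unlist(corpus$supp_sample)))
}

# brute-force classifier oracle: regex-free character scan, written
# independently of classify_filename()
oracle_substring_hit <- function(name, token) {
  a <- utf8ToInt(tolower(name)); b <- utf8ToInt(tolower(token))
  if (length(b) > length(a)) return(FALSE)
  for (start in seq_len(length(a) - length(b) + 1)) {
    if (all(a[start:(start + length(b) - 1)] == b)) return(TRUE)
  }
  FALSE
}

oracle_extension_hit <- function(name, token) {
  n <- tolower(name)
  for (suf in c(".gz", ".bz2", ".zip")) {
    ls <- nchar(suf)
    if (nchar(n) > ls && substr(n, nchar(n) - ls + 1, nchar(n)) == suf) {
      n <- substr(n, 1, nchar(n) - ls)
      break
    }
  }
  chars <- strsplit(n, "")[[1]]
  dots <- which(chars == ".")
  if (length(dots) == 0) return(FALSE)
  ext <- chars[seq(max(dots) + 1, length.out = length(chars) - max(dots))]
  tk <- strsplit(tolower(token), "")[[1]]
  length(ext) >= length(tk) && all(ext[seq_along(tk)] == tk)
}

oracle_classify <- function(name, rules = pattern_rules()) {
  base <- basename(name)
  any(vapply(rules$name_substrings, oracle_substring_hit, logical(1),
             name = base)) ||
    any(vapply(rules$object_extensions, oracle_extension_hit, logical(1),
               name = base))
}

# every filename the synthetic generator can emit, with templates filled
synthetic_vocabulary <- function() {
  templates <- c(scmetaudit:::synth_metadata_vocab(),
                 scmetaudit:::synth_missed_vocab(),
                 scmetaudit:::synth_decoy_vocab(),
                 scmetaudit:::synth_neutral_vocab())
  unique(scmetaudit:::fill_acc(templates, "SYN000123"))
}

paper_counts <- function() validation_counts(173, 156, 27, 24, 10, 22)
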