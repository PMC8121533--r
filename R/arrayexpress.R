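#' Default ArrayExpress query term
#'
#' The recommended experiment-type term for retrieving droplet and
#' well-based single-cell RNA-seq submissions from ArrayExpress/BioStudies.
#'
#' @return A string.
#' @export
ae_default_query <- function() "RNA-seq of coding RNA from single cells"

#' Construct an ArrayExpress entry
#'
#' @param accession E-MTAB-style identifier.
#' @param library_construction Free-text "library construction" annotation
#'   (the field used to restrict the audit to droplet platforms).
#' @param idf_filenames,sdrf_filenames Filenames extracted from the entry's
#'   IDF and SDRF documents (see [extract_filenames()]).
#' @return A one-row tibble; bind rows to build an entry set.
#' @export
ae_entry <- function(accession, library_construction = "",
                     idf_filenames = character(),
                     sdrf_filenames = character()) {
  if (length(accession) != 1 || is.na(accession) || !nzchar(accession)) {
    stop("ArrayExpress entry requires a nonempty accession", call. = FALSE)
  }
  if (!grepl("^E-[A-Z]{4}-[0-9]+$", accession)) {
    stop("accession '", accession, "' does not match the E-XXXX-n pattern",
         call. = FALSE)
  }
  tibble::tibble(
    accession = accession,
    library_construction = as.character(library_construction),
    idf_filenames = list(basename(idf_filenames)),
    sdrf_filenames = list(basename(sdrf_filenames))
  )
}

#' Restrict entries to 10x Genomics (droplet) datasets
#'
#' Droplet platforms are the cases where ArrayExpress sample-level metadata
#' cannot carry per-cell annotations, so the deposition audit is restricted
#' to them. Matching is case-insensitive substring over the
#' `library_construction` field.
#'
#' @param entries A tibble of entries (rows from [ae_entry()]).
#' @param terms Platform term list; any hit retains the entry.
#' @return The retained subset.
#' @export
#' @examples
#' e <- dplyr::bind_rows(ae_entry("E-MTAB-6701", "10x Genomics 3' v2"),
#'                       ae_entry("E-MTAB-0001", "Smart-seq2"))
#' filter_10x(e)$accession
filter_10x <- function(entries, terms = "10x") {
  entries <- tibble::as_tibble(entries)
  lc <- tolower(entries$library_construction)
  keep <- Reduce(`|`, lapply(tolower(terms), function(t) {
    vapply(lc, grepl, logical(1), pattern = t, fixed = TRUE, USE.NAMES = FALSE)
  }))
  entries[keep, , drop = FALSE]
}

#' Extract data-file names from IDF and SDRF documents
#'
#' SDRF: every value in a column whose header contains "file"
#' (case-insensitive) is taken. IDF: values on rows whose key mentions
#' "file". Results are reduced to basenames and deduplicated, preserving
#' first-occurrence order.
#'
#' @param idf_text IDF document as a character scalar or vector of lines
#'   (tab-delimited key/value rows); may be `NULL`.
#' @param sdrf_text SDRF document as a character scalar or vector of lines
#'   (tab-delimited with a header row); may be `NULL`.
#' @return Character vector of unique file basenames.
#' @export
extract_filenames <- function(idf_text = NULL, sdrf_text = NULL) {
  as_lines <- function(x) {
    if (is.null(x)) return(character())
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  out <- character()
  idf <- as_lines(idf_text)
  idf <- idf[nzchar(trimws(idf))]
  for (line in idf) {
    cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cells) >= 2 && grepl("file", cells[1], ignore.case = TRUE)) {
      out <- c(out, cells[-1])
    }
  }
  sdrf <- as_lines(sdrf_text)
  sdrf <- sdrf[nzchar(trimws(sdrf))]
  if (length(sdrf) >= 1) {
    header <- strsplit(sdrf[1], "\t", fixed = TRUE)[[1]]
    if (length(sdrf) > 1 && length(header) == 1 && !grepl("\t", sdrf[1])) {
      stop("SDRF input does not look tab-delimited", call. = FALSE)
    }
    file_cols <- grep("file", header, ignore.case = TRUE)
    for (line in sdrf[-1]) {
      cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
      hit <- file_cols[file_cols <= length(cells)]
      out <- c(out, cells[hit])
    }
  }
  out <- basename(trimws(out))
  unique(out[nzchar(out)])
}

#' Convert ArrayExpress entries into a record corpus
#'
#' Filenames from both documents are pooled as series-level supplementary
#' names so the GEO classifier applies unchanged.
#'
#' @param entries A tibble of entries.
#' @param snapshot_date Harvest snapshot date.
#' @return A [record_corpus()] with source `"arrayexpress"`.
#' @export
ae_as_corpus <- function(entries, snapshot_date = Sys.Date()) {
  entries <- tibble::as_tibble(entries)
  records <- lapply(seq_len(nrow(entries)), function(i) {
    repo_record(
      accession = entries$accession[[i]],
      record_type = "series",
      supp_series = unique(c(entries$idf_filenames[[i]],
                             entries$sdrf_filenames[[i]])),
      library_strategy_text = entries$library_construction[[i]]
    )
  })
  record_corpus(records, snapshot_date = snapshot_date, source = "arrayexpress")
}

#' Audit cell-level metadata deposition in ArrayExpress entries
#'
#' Applies the shared filename rule set to the file names extracted from
#' each (10x-filtered) entry's IDF/SDRF documents and reports the detected
#' fraction.
#'
#' @param entries A tibble of 10x-filtered entries.
#' @param rules A [pattern_rules()] object; the same object used for the GEO
#'   audit, so any rule change affects both audits identically.
#' @return A list of class `detected_fraction` (see [detected_fraction()]),
#'   plus per-entry verdicts in its `verdicts` element.
#' @export
audit_arrayexpress <- function(entries, rules = pattern_rules()) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) {
    stop("empty corpus: no ArrayExpress entries to audit", call. = FALSE)
  }
  corpus <- ae_as_corpus(entries)
  res <- detected_fraction(corpus, rules = rules, scope = "series_level")
  res$verdicts <- classify_corpus(corpus, rules = rules, scope = "series_level")
  res
}
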