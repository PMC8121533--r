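#' Construct a repository record
#'
#' A repository record is the unit the audit operates on: one GEO series
#' (or ArrayExpress entry mapped into the same shape), with its descriptive
#' text fields and the names of its supplementary processed-data files.
#' Supplementary files attached at the sample level are kept separately from
#' series-level files so audits can be restricted to series-level names only
#' (the default throughout the package).
#'
#' @param accession Series identifier, e.g. `"GSE137710"`. Required, nonempty.
#' @param title,summary,overall_design Free-text descriptive fields.
#' @param record_type One of `"series"`, `"superseries"`, `"subseries"`.
#' @param related_accessions Character vector of related series: the
#'   subseries of a superseries, or the parent of a subseries.
#' @param supp_series,supp_sample Character vectors of supplementary file
#'   basenames at series and sample level. URL/path components are stripped;
#'   empty entries dropped.
#' @param submission_date A `Date` (or string coercible to one), or `NA`.
#' @param publication_id Linked PubMed identifier as a string, or `NA`.
#' @param library_strategy_text Free text describing the library strategy /
#'   dataset type. GEO has no single-cell-specific library term, so this is
#'   only ever keyword-filtered, never used as a structured field.
#'
#' @return A list of class `repo_record`.
#' @export
#' @examples
#' repo_record("GSE1", title = "scRNA-seq of melanoma",
#'             supp_series = "GSE1_cell_metadata.tsv.gz")
repo_record <- function(accession,
                        title = "",
                        summary = "",
                        overall_design = "",
                        record_type = c("series", "superseries", "subseries"),
                        related_accessions = character(),
                        supp_series = character(),
                        supp_sample = character(),
                        submission_date = as.Date(NA),
                        publication_id = NA_character_,
                        library_strategy_text = "") {
  if (length(accession) != 1 || is.na(accession) || !nzchar(accession)) {
    stop("malformed record: accession must be a nonempty string", call. = FALSE)
  }
  record_type <- match.arg(record_type)
  clean <- function(x) {
    x <- as.character(x)
    x <- trimws(x)
    basename(x[!is.na(x) & nzchar(x)])
  }
  rec <- list(
    accession = as.character(accession),
    title = as.character(title %||% ""),
    summary = as.character(summary %||% ""),
    overall_design = as.character(overall_design %||% ""),
    record_type = record_type,
    related_accessions = unique(clean(related_accessions)),
    supp_series = clean(supp_series),
    supp_sample = clean(supp_sample),
    submission_date = as.Date(submission_date),
    publication_id = if (is.na(publication_id)) NA_character_ else as.character(publication_id),
    library_strategy_text = as.character(library_strategy_text %||% "")
  )
  structure(rec, class = "repo_record")
}

#' @export
print.repo_record <- function(x, ...) {
  cat("<repo_record> ", x$accession, " [", x$record_type, "]\n", sep = "")
  if (nzchar(x$title)) cat("  title: ", x$title, "\n", sep = "")
  cat("  supplementary files: ", length(x$supp_series), " series-level, ",
      length(x$supp_sample), " sample-level\n", sep = "")
  invisible(x)
}

record_fields <- c(
  "accession", "title", "summary", "overall_design", "record_type",
  "related_accessions", "supp_series", "supp_sample", "submission_date",
  "publication_id", "library_strategy_text"
)

#' Assemble records into a corpus
#'
#' A record corpus is a tibble with one row per record (list-columns for
#' related accessions and filename lists) carrying the harvest snapshot date
#' and source as attributes. Duplicate accessions are collapsed keeping the
#' first occurrence, with a warning naming the collisions.
#'
#' @param records A list of [repo_record()] objects (or a single record).
#' @param snapshot_date Harvest snapshot date.
#' @param source One of `"geo"`, `"arrayexpress"`, `"synthetic"`.
#' @return A tibble of class `record_corpus`.
#' @export
record_corpus <- function(records, snapshot_date = Sys.Date(),
                          source = c("geo", "arrayexpress", "synthetic")) {
  source <- match.arg(source)
  if (inherits(records, "repo_record")) records <- list(records)
  if (length(records) == 0) {
    stop("empty corpus: no records supplied", call. = FALSE)
  }
  stopifnot(all(vapply(records, inherits, logical(1), "repo_record")))
  acc <- vapply(records, `[[`, character(1), "accession")
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    warning("duplicate accessions collapsed (keeping first): ",
            paste(dup, collapse = ", "), call. = FALSE)
    records <- records[!duplicated(acc)]
  }
  tbl <- tibble::tibble(
    accession = vapply(records, `[[`, character(1), "accession"),
    title = vapply(records, `[[`, character(1), "title"),
    summary = vapply(records, `[[`, character(1), "summary"),
    overall_design = vapply(records, `[[`, character(1), "overall_design"),
    record_type = vapply(records, `[[`, character(1), "record_type"),
    related_accessions = lapply(records, `[[`, "related_accessions"),
    supp_series = lapply(records, `[[`, "supp_series"),
    supp_sample = lapply(records, `[[`, "supp_sample"),
    submission_date = as.Date(vapply(records, function(r) as.character(r$submission_date), character(1))),
    publication_id = vapply(records, `[[`, character(1), "publication_id"),
    library_strategy_text = vapply(records, `[[`, character(1), "library_strategy_text")
  )
  new_record_corpus(tbl, snapshot_date = snapshot_date, source = source)
}

new_record_corpus <- function(tbl, snapshot_date, source) {
  structure(tbl,
            snapshot_date = as.Date(snapshot_date),
            corpus_source = source,
            class = c("record_corpus", class(tibble::as_tibble(tbl))))
}

#' @export
print.record_corpus <- function(x, ...) {
  cat("<record_corpus> ", nrow(x), " records; source = ",
      attr(x, "corpus_source"), "; snapshot = ",
      format(attr(x, "snapshot_date")), "\n", sep = "")
  NextMethod()
}

#' Extract one record from a corpus row
#' @param corpus A `record_corpus`.
#' @param i Row index or accession string.
#' @return A [repo_record()].
#' @export
corpus_record <- function(corpus, i) {
  if (is.character(i)) i <- match(i, corpus$accession)
  if (is.na(i) || i < 1 || i > nrow(corpus)) {
    stop("record not found in corpus", call. = FALSE)
  }
  repo_record(
    accession = corpus$accession[[i]],
    title = corpus$title[[i]],
    summary = corpus$summary[[i]],
    overall_design = corpus$overall_design[[i]],
    record_type = corpus$record_type[[i]],
    related_accessions = corpus$related_accessions[[i]],
    supp_series = corpus$supp_series[[i]],
    supp_sample = corpus$supp_sample[[i]],
    submission_date = corpus$submission_date[[i]],
    publication_id = corpus$publication_id[[i]],
    library_strategy_text = corpus$library_strategy_text[[i]]
  )
}

#' Parse one repository record from raw text
#'
#' Three cached-record dialects are supported:
#' \describe{
#'   \item{`soft`}{A GEO SOFT series block (`!Series_*` lines; sample-level
#'     `!Sample_supplementary_file*` lines are pooled into the record's
#'     sample-level list).}
#'   \item{`docsum`}{A simplified E-utilities DocSum XML `<DocSum>` element
#'     with `Item` children named `Accession`, `title`, `summary`,
#'     `suppFile`, `PDAT`, `PubMedIds` and optionally `Relations`.}
#'   \item{`tabular`}{One tab-delimited row of the corpus interchange format
#'     written by [write_corpus()] (filename lists pipe-delimited).}
#' }
#' Supplementary file entries are reduced to basenames (FTP URLs and paths
#' stripped) and surrounding whitespace removed.
#'
#' @param raw_text Character scalar (or vector of lines) holding one record.
#' @param dialect One of `"soft"`, `"docsum"`, `"tabular"`.
#' @return A [repo_record()].
#' @export
#' @examples
#' soft <- c("!Series_geo_accession = GSE137710",
#'           "!Series_title = Melanoma and spleen single cell RNA-seq",
#'           paste0("!Series_supplementary_file = ftp://ftp.ncbi.nlm.nih.gov/",
#'                  "geo/suppl/GSE137710_human_melanoma_cell_metadata_9315x14.tsv.gz"))
#' parse_record(soft, dialect = "soft")
parse_record <- function(raw_text, dialect = c("soft", "docsum", "tabular")) {
  dialect <- match.arg(dialect)
  if (length(raw_text) == 0 || all(!nzchar(trimws(raw_text)))) {
    stop("malformed record: empty input for dialect '", dialect, "'",
         call. = FALSE)
  }
  switch(dialect,
         soft = parse_soft_block(raw_text),
         docsum = parse_docsum_block(raw_text),
         tabular = parse_tabular_row(raw_text))
}

soft_field <- function(lines, key) {
  pat <- paste0("^!Series_", key, "\\s*=\\s*")
  hits <- grep(pat, lines, value = TRUE)
  sub(pat, "", hits)
}

parse_soft_block <- function(raw_text) {
  lines <- unlist(strsplit(raw_text, "\n", fixed = TRUE), use.names = FALSE)
  acc <- soft_field(lines, "geo_accession")
  if (length(acc) == 0) {
    carat <- grep("^\\^SERIES\\s*=\\s*", lines, value = TRUE)
    acc <- sub("^\\^SERIES\\s*=\\s*", "", carat)
  }
  if (length(acc) == 0 || !nzchar(trimws(acc[1]))) {
    stop("malformed record: no accession found in SOFT block", call. = FALSE)
  }
  relations <- soft_field(lines, "relation")
  super_of <- sub("^SuperSeries of:\\s*", "",
                  grep("^SuperSeries of:", relations, value = TRUE))
  sub_of <- sub("^SubSeries of:\\s*", "",
                grep("^SubSeries of:", relations, value = TRUE))
  record_type <- if (length(super_of) > 0) "superseries"
                 else if (length(sub_of) > 0) "subseries"
                 else "series"
  date_raw <- soft_field(lines, "submission_date")[1]
  sdate <- parse_geo_date(date_raw)
  pmid <- soft_field(lines, "pubmed_id")[1]
  samp_pat <- "^!Sample_supplementary_file[^=]*=\\s*"
  samp_hits <- grep(samp_pat, lines, value = TRUE)
  supp_sample <- sub(samp_pat, "", samp_hits)
  supp_sample <- supp_sample[!tolower(trimws(supp_sample)) %in% c("none", "")]
  supp_series <- soft_field(lines, "supplementary_file")
  supp_series <- supp_series[!tolower(trimws(supp_series)) %in% c("none", "")]
  repo_record(
    accession = trimws(acc[1]),
    title = paste(soft_field(lines, "title"), collapse = " "),
    summary = paste(soft_field(lines, "summary"), collapse = " "),
    overall_design = paste(soft_field(lines, "overall_design"), collapse = " "),
    record_type = record_type,
    related_accessions = c(super_of, sub_of),
    supp_series = supp_series,
    supp_sample = supp_sample,
    submission_date = sdate,
    publication_id = if (length(pmid) == 0 || is.na(pmid)) NA_character_ else trimws(pmid),
    library_strategy_text = paste(soft_field(lines, "type"), collapse = "; ")
  )
}

parse_geo_date <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(trimws(x))) return(as.Date(NA))
  x <- trimws(x)
  d <- suppressWarnings(as.Date(x, format = "%b %d %Y"))
  if (is.na(d)) d <- suppressWarnings(as.Date(x))
  d
}

parse_docsum_block <- function(raw_text) {
  txt <- paste(raw_text, collapse = "\n")
  doc <- tryCatch(xml2::read_xml(txt), error = function(e) {
    stop("malformed record: unparseable DocSum XML (", conditionMessage(e), ")",
         call. = FALSE)
  })
  node <- if (xml2::xml_name(doc) == "DocSum") doc else xml2::xml_find_first(doc, ".//DocSum")
  if (is.na(node) || length(node) == 0) {
    stop("malformed record: no <DocSum> element found", call. = FALSE)
  }
  item <- function(name) {
    n <- xml2::xml_find_first(node, paste0("./Item[@Name='", name, "']"))
    if (is.na(n) || length(n) == 0) return(NA_character_)
    xml2::xml_text(n)
  }
  acc <- item("Accession")
  if (is.na(acc) || !nzchar(trimws(acc))) {
    stop("malformed record: DocSum lacks an Accession item", call. = FALSE)
  }
  supp <- item("suppFile")
  supp <- if (is.na(supp)) character() else trimws(strsplit(supp, "[;,]")[[1]])
  pmids <- xml2::xml_text(xml2::xml_find_all(
    node, "./Item[@Name='PubMedIds']/Item"))
  rel <- item("Relations")
  rels <- if (is.na(rel)) character() else trimws(strsplit(rel, ";")[[1]])
  super_of <- sub("^SuperSeries of:\\s*", "",
                  grep("^SuperSeries of:", rels, value = TRUE))
  sub_of <- sub("^SubSeries of:\\s*", "",
                grep("^SubSeries of:", rels, value = TRUE))
  record_type <- if (length(super_of) > 0) "superseries"
                 else if (length(sub_of) > 0) "subseries"
                 else "series"
  repo_record(
    accession = trimws(acc),
    title = item("title") %|NA|% "",
    summary = item("summary") %|NA|% "",
    record_type = record_type,
    related_accessions = c(super_of, sub_of),
    supp_series = supp,
    submission_date = parse_geo_date(item("PDAT")),
    publication_id = if (length(pmids) > 0) pmids[1] else NA_character_,
    library_strategy_text = item("gdsType") %|NA|% ""
  )
}

tabular_columns <- c(
  "accession", "title", "summary", "overall_design", "record_type",
  "related_accessions", "supp_series", "supp_sample", "submission_date",
  "publication_id", "library_strategy_text"
)

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

parse_tabular_row <- function(raw_text) {
  line <- paste(raw_text, collapse = "")
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  length(parts) <- length(tabular_columns)
  parts[is.na(parts)] <- ""
  names(parts) <- tabular_columns
  if (!nzchar(trimws(parts[["accession"]]))) {
    stop("malformed record: tabular row lacks an accession", call. = FALSE)
  }
  rectype <- trimws(parts[["record_type"]])
  repo_record(
    accession = trimws(parts[["accession"]]),
    title = parts[["title"]],
    summary = parts[["summary"]],
    overall_design = parts[["overall_design"]],
    record_type = if (nzchar(rectype)) rectype else "series",
    related_accessions = split_pipe(parts[["related_accessions"]]),
    supp_series = split_pipe(parts[["supp_series"]]),
    supp_sample = split_pipe(parts[["supp_sample"]]),
    submission_date = parse_geo_date(parts[["submission_date"]]),
    publication_id = if (nzchar(trimws(parts[["publication_id"]])))
      trimws(parts[["publication_id"]]) else NA_character_,
    library_strategy_text = parts[["library_strategy_text"]]
  )
}

#' Load a cached record corpus from disk
#'
#' Reads a whole file of records in one of the supported dialects. SOFT files
#' may concatenate many series blocks (split on `^SERIES` carets or on
#' `!Series_geo_accession` lines); DocSum files hold an
#' `<eSummaryResult>`/`<DocSumSet>` with multiple `<DocSum>` children; tabular
#' files are the interchange format of [write_corpus()] (header row, optional
#' `#key=value` comment lines carrying snapshot date and source).
#'
#' @param path Readable file path.
#' @param source Corpus source label; defaults to the file's `#source=`
#'   comment for tabular input, else `"geo"`.
#' @param dialect `"soft"`, `"docsum"` or `"tabular"`; guessed from the file
#'   extension when `NULL` (`.soft` / `.xml` / anything else tabular).
#' @return A [record_corpus()].
#' @export
load_corpus <- function(path, source = NULL, dialect = NULL) {
  if (!file.exists(path)) {
    stop("cannot read corpus: no such file '", path, "'", call. = FALSE)
  }
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      soft = "soft", xml = "docsum", "tabular")
  }
  lines <- readr::read_lines(path)
  meta <- list(snapshot_date = Sys.Date(), source = source)
  records <- switch(
    dialect,
    soft = {
      idx <- grep("^\\^SERIES", lines)
      if (length(idx) == 0) idx <- grep("^!Series_geo_accession", lines)
      if (length(idx) == 0) list() else {
        bounds <- c(idx, length(lines) + 1L)
        lapply(seq_along(idx), function(i) {
          parse_record(lines[bounds[i]:(bounds[i + 1] - 1L)], "soft")
        })
      }
    },
    docsum = {
      doc <- xml2::read_xml(paste(lines, collapse = "\n"))
      nodes <- xml2::xml_find_all(doc, "//DocSum")
      lapply(nodes, function(n) parse_record(as.character(n), "docsum"))
    },
    tabular = {
      kv <- grep("^#", lines, value = TRUE)
      for (l in kv) {
        m <- regmatches(l, regexec("^#\\s*(\\w+)\\s*=\\s*(.*)$", l))[[1]]
        if (length(m) == 3) {
          if (m[2] == "snapshot_date") meta$snapshot_date <- as.Date(m[3])
          if (m[2] == "source" && is.null(meta$source)) meta$source <- m[3]
        }
      }
      body <- lines[!grepl("^#", lines) & nzchar(lines)]
      if (length(body) >= 1 &&
          identical(strsplit(body[1], "\t")[[1]][1], "accession")) {
        body <- body[-1]
      }
      lapply(body, parse_record, dialect = "tabular")
    },
    stop("unknown dialect '", dialect, "'", call. = FALSE)
  )
  if (length(records) == 0) {
    stop("empty corpus: no parseable records in '", path, "'", call. = FALSE)
  }
  record_corpus(records,
                snapshot_date = meta$snapshot_date,
                source = meta$source %||% "geo")
}

#' Write a corpus in the tabular interchange dialect
#'
#' One tab-delimited row per record; filename and relation lists are
#' pipe-delimited; snapshot date and source are stored as `#key=value`
#' comment lines so [load_corpus()] round-trips the corpus exactly.
#'
#' @param corpus A `record_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "record_corpus"))
  join_pipe <- function(x) paste(x, collapse = "|")
  rows <- vapply(seq_len(nrow(corpus)), function(i) {
    paste(c(
      corpus$accession[[i]], corpus$title[[i]], corpus$summary[[i]],
      corpus$overall_design[[i]], corpus$record_type[[i]],
      join_pipe(corpus$related_accessions[[i]]),
      join_pipe(corpus$supp_series[[i]]),
      join_pipe(corpus$supp_sample[[i]]),
      if (is.na(corpus$submission_date[[i]])) "" else format(corpus$submission_date[[i]]),
      if (is.na(corpus$publication_id[[i]])) "" else corpus$publication_id[[i]],
      corpus$library_strategy_text[[i]]
    ), collapse = "\t")
  }, character(1))
  header <- c(
    paste0("#source=", attr(corpus, "corpus_source")),
    paste0("#snapshot_date=", format(attr(corpus, "snapshot_date"))),
    paste(tabular_columns, collapse = "\t")
  )
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x
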