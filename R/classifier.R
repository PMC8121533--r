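#' Filename pattern rules for detecting cell-level metadata
#'
#' Two rule families decide, from a supplementary file's name alone, whether
#' it plausibly carries cell-level metadata: (1) name substrings drawn from
#' the vocabulary analysis suites use when exporting per-cell tables
#' ("meta", "annot", "type", "clustering", "coldata"); (2) extensions of R-
#' and Python-readable object formats that bundle such tables ("rds", "rda",
#' "rdata", "loom", "h5ad"). Both families match case-insensitively. The
#' substring family intentionally over-matches (e.g. "genotype", gene
#' "annotation" files); the spot-check correction in
#' [corrected_prevalence()] quantifies exactly that error, so the defaults
#' must not be "improved" when mirroring the audit.
#'
#' @param name_substrings Case-insensitive substrings matched anywhere in the
#'   basename.
#' @param object_extensions Case-insensitive extension tokens. After
#'   stripping at most one trailing compression suffix (`.gz`, `.bz2`,
#'   `.zip`), a token matches when the file's final extension starts with
#'   it — so `.rdata` triggers both the `rda` and `rdata` tokens, which is
#'   intended (OR semantics; both matches are recorded).
#' @param extension_mode `"extension"` (default) for true-extension
#'   semantics, or `"substring"` to also count the token anywhere in the
#'   name (sensitivity analysis only).
#' @return A list of class `pattern_rules`.
#' @export
pattern_rules <- function(name_substrings = c("meta", "annot", "type",
                                              "clustering", "coldata"),
                          object_extensions = c("rds", "rda", "rdata",
                                                "loom", "h5ad"),
                          extension_mode = c("extension", "substring")) {
  extension_mode <- match.arg(extension_mode)
  default <- missing(name_substrings) && missing(object_extensions)
  if (!default) {
    message("non-default classifier rules in use; audits are not comparable ",
            "with the default rule set")
  }
  structure(list(name_substrings = tolower(name_substrings),
                 object_extensions = tolower(object_extensions),
                 extension_mode = extension_mode),
            class = "pattern_rules")
}

#' @export
print.pattern_rules <- function(x, ...) {
  cat("<pattern_rules>\n",
      "  substrings: ", paste(x$name_substrings, collapse = ", "), "\n",
      "  extensions: ", paste(x$object_extensions, collapse = ", "),
      " (", x$extension_mode, " mode)\n", sep = "")
  invisible(x)
}

strip_compression <- function(name) {
  sub("\\.(gz|bz2|zip)$", "", name, ignore.case = TRUE)
}

#' Classify a single filename
#'
#' Returns every rule the basename triggers, in rule order (substrings
#' first). A substring rule matches anywhere in the name; an extension rule
#' matches when the name, after stripping one compression suffix, ends in
#' `.token`.
#'
#' @param name Nonempty filename (paths allowed; only the basename is used).
#' @param rules A [pattern_rules()] object.
#' @return A tibble with columns `filename`, `rule`, `rule_kind`
#'   (`"substring"` or `"extension"`); zero rows when nothing matches.
#' @export
#' @examples
#' classify_filename("GSE137710_human_melanoma_cell_metadata_9315x14.tsv.gz")
#' classify_filename("raw_data_10x.txt")   # no match
classify_filename <- function(name, rules = pattern_rules()) {
  if (length(name) != 1 || is.na(name) || !nzchar(name)) {
    stop("classify_filename requires a nonempty filename", call. = FALSE)
  }
  stopifnot(inherits(rules, "pattern_rules"))
  base <- tolower(basename(trimws(name)))
  sub_hit <- vapply(rules$name_substrings, function(s) grepl(s, base, fixed = TRUE),
                    logical(1))
  stripped <- strip_compression(base)
  final_ext <- if (grepl(".", stripped, fixed = TRUE)) {
    sub(".*\\.", "", stripped)
  } else ""
  ext_hit <- vapply(rules$object_extensions, function(e) {
    if (rules$extension_mode == "substring") {
      grepl(e, base, fixed = TRUE)
    } else {
      nzchar(final_ext) && startsWith(final_ext, e)
    }
  }, logical(1))
  tibble::tibble(
    filename = basename(trimws(name)),
    rule = c(rules$name_substrings[sub_hit], rules$object_extensions[ext_hit]),
    rule_kind = c(rep("substring", sum(sub_hit)), rep("extension", sum(ext_hit)))
  )
}

record_filenames <- function(record, scope) {
  get <- function(f) {
    v <- record[[f]]
    if (is.list(v)) v <- v[[1]]
    if (is.null(v)) character() else as.character(v)
  }
  if (scope == "all_levels") c(get("supp_series"), get("supp_sample"))
  else get("supp_series")
}

#' Classify one record's supplementary files
#'
#' A record is called positive when any supplementary filename in scope
#' triggers at least one rule. The default scope is series-level files only,
#' mirroring series-level extraction; `"all_levels"` additionally scans
#' sample-level attachments.
#'
#' @param record A [repo_record()] or one-row corpus slice.
#' @inheritParams classify_filename
#' @param scope `"series_level"` (default) or `"all_levels"`.
#' @return A list of class `classifier_verdict`: `accession`, `positive`,
#'   and a `matched` tibble of (filename, rule, rule_kind).
#' @export
classify_record <- function(record, rules = pattern_rules(),
                            scope = c("series_level", "all_levels")) {
  scope <- match.arg(scope)
  acc <- record[["accession"]]
  if (is.list(acc)) acc <- acc[[1]]
  files <- record_filenames(record, scope)
  files <- files[!is.na(files) & nzchar(files)]
  matched <- if (length(files) == 0) {
    tibble::tibble(filename = character(), rule = character(),
                   rule_kind = character())
  } else {
    dplyr::bind_rows(lapply(files, classify_filename, rules = rules))
  }
  structure(list(accession = as.character(acc),
                 positive = nrow(matched) > 0,
                 matched = matched),
            class = "classifier_verdict")
}

#' @export
print.classifier_verdict <- function(x, ...) {
  cat("<classifier_verdict> ", x$accession, ": ",
      if (x$positive) "POSITIVE" else "negative", "\n", sep = "")
  if (nrow(x$matched) > 0) print(x$matched)
  invisible(x)
}

#' Classify every record in a corpus
#'
#' @param corpus A `record_corpus`.
#' @inheritParams classify_record
#' @return A tibble with one row per record: `accession`, `positive`,
#'   `n_matches`, `matched` (list-column of match tibbles).
#' @export
classify_corpus <- function(corpus, rules = pattern_rules(),
                            scope = c("series_level", "all_levels")) {
  scope <- match.arg(scope)
  stopifnot(inherits(corpus, "record_corpus"))
  verdicts <- lapply(seq_len(nrow(corpus)), function(i) {
    classify_record(corpus[i, , drop = FALSE], rules = rules, scope = scope)
  })
  tibble::tibble(
    accession = vapply(verdicts, `[[`, character(1), "accession"),
    positive = vapply(verdicts, `[[`, logical(1), "positive"),
    n_matches = vapply(verdicts, function(v) nrow(v$matched), integer(1)),
    matched = lapply(verdicts, `[[`, "matched")
  )
}

#' Detected fraction of metadata-positive records
#'
#' The raw audit headline: the proportion of (merged) records whose
#' supplementary filenames trigger the classifier. Exact counts are returned
#' alongside the percentage rounded to one decimal (round-half-even).
#'
#' @param corpus A merged `record_corpus` (no subseries rows).
#' @inheritParams classify_record
#' @return A list of class `detected_fraction`: `n_positive`, `n_records`,
#'   `fraction`, `percent` (one decimal).
#' @export
detected_fraction <- function(corpus, rules = pattern_rules(),
                              scope = c("series_level", "all_levels")) {
  scope <- match.arg(scope)
  stopifnot(inherits(corpus, "record_corpus"))
  if (nrow(corpus) == 0) {
    stop("empty corpus: detected fraction undefined", call. = FALSE)
  }
  if (any(corpus$record_type == "subseries")) {
    stop("corpus contains unmerged subseries; run merge_superseries() first",
         call. = FALSE)
  }
  verdicts <- classify_corpus(corpus, rules = rules, scope = scope)
  n_pos <- sum(verdicts$positive)
  structure(list(
    n_positive = n_pos,
    n_records = nrow(corpus),
    fraction = n_pos / nrow(corpus),
    percent = round(100 * n_pos / nrow(corpus), 1)
  ), class = "detected_fraction")
}

#' @export
print.detected_fraction <- function(x, ...) {
  cat("detected cell-level metadata in ", x$n_positive, "/", x$n_records,
      " records (", format(x$percent, nsmall = 1), "%)\n", sep = "")
  invisible(x)
}
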