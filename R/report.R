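#' Run the full deposition audit
#'
#' Chains the pipeline stages over a cached or synthetic corpus: load (or
#' generate) records, keyword-filter, merge SuperSeries families, classify
#' supplementary filenames, compute the detected fraction, and — when
#' spot-check counts are supplied — the misclassification-corrected
#' prevalence. Optional publication info adds the year / journal-group /
#' tool-author stratifications.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Recognised keys:
#' \describe{
#'   \item{`corpus`}{Path of a cached corpus file (any dialect
#'     [load_corpus()] reads), or}
#'   \item{`synth`}{a list of [corpus_spec()] arguments to generate a
#'     synthetic corpus instead.}
#'   \item{`keyword_filter`}{Apply the single-cell keyword filter first
#'     (default `TRUE`).}
#'   \item{`scope`}{Classifier scope, default `"series_level"`.}
#'   \item{`rules`}{List with `name_substrings` / `object_extensions` /
#'     `extension_mode` overriding the default [pattern_rules()].}
#'   \item{`validation_counts`}{Path of a spot-check counts file
#'     ([read_validation_counts()]) or a named list of counts.}
#'   \item{`detected_rate`}{Override the corpus detected rate fed into the
#'     correction (e.g. a published corpus-level rate); defaults to the rate
#'     measured on the corpus.}
#'   \item{`upper_bound`}{Headline cap in percent (default 25).}
#'   \item{`pubs`}{Path of a publication-info table (TSV) or a data frame.}
#'   \item{`journal_grouping`}{Path of a two-column journal/group TSV or a
#'     named vector.}
#'   \item{`citation_years`, `tool_author_since`}{Stratification controls.}
#'   \item{`out_dir`}{Directory for report files; no files written if NULL.}
#' }
#' @param quiet Suppress progress messages.
#' @return A list of class `audit_summary` with the corpus size, verdicts,
#'   detected fraction, prevalence estimate (or NULL), stratified summaries
#'   (or NULL), the rule set used, and provenance.
#' @export
run_audit <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message(...)

  rules <- if (is.null(config$rules)) pattern_rules() else {
    do.call(pattern_rules, config$rules)
  }
  scope <- config$scope %||% "series_level"

  truth <- NULL
  pubs <- config$pubs
  if (!is.null(config$synth)) {
    say("stage synth: generating synthetic corpus")
    gen <- generate_corpus(do.call(corpus_spec, config$synth))
    corpus <- gen$corpus
    truth <- gen$truth
    if (is.null(pubs)) pubs <- gen$pubs
  } else if (!is.null(config$corpus)) {
    say("stage load: reading corpus from ", config$corpus)
    corpus <- load_corpus(config$corpus)
  } else {
    stop("stage load: config names neither a corpus file nor a synth spec",
         call. = FALSE)
  }

  if (isTRUE(config$keyword_filter %||% TRUE)) {
    n0 <- nrow(corpus)
    corpus <- filter_keywords(corpus)
    say("stage filter: ", nrow(corpus), "/", n0, " records retained")
    if (nrow(corpus) == 0) {
      stop("stage filter: no records retained by the keyword filter",
           call. = FALSE)
    }
  }
  corpus <- merge_superseries(corpus)
  say("stage merge: ", nrow(corpus), " records after SuperSeries merging")

  verdicts <- classify_corpus(corpus, rules = rules, scope = scope)
  detected <- detected_fraction(corpus, rules = rules, scope = scope)
  say("stage classify: detected fraction ", detected$percent, "% (",
      detected$n_positive, "/", detected$n_records, ")")

  prevalence <- NULL
  if (!is.null(config$validation_counts)) {
    counts <- config$validation_counts
    counts <- if (is.character(counts)) read_validation_counts(counts)
              else do.call(validation_counts, counts)
    d <- config$detected_rate %||% detected$fraction
    prevalence <- corrected_prevalence(d, counts,
                                       upper_bound = config$upper_bound %||% 25)
    say("stage validate: corrected prevalence ",
        prevalence$corrected_percent, "%")
  }

  strata <- NULL
  if (!is.null(pubs)) {
    if (is.character(pubs)) {
      pubs <- utils::read.delim(pubs, stringsAsFactors = FALSE)
    }
    pubs$publication_id <- as.character(pubs$publication_id)
    annotated <- join_publications(corpus, tibble::as_tibble(pubs))
    strata <- list(by_year = fraction_by_year(annotated, verdicts))
    grouping <- config$journal_grouping
    if (!is.null(grouping)) {
      if (is.character(grouping) && length(grouping) == 1 && file.exists(grouping)) {
        grouping <- utils::read.delim(grouping, stringsAsFactors = FALSE)
      }
      strata$by_group <- fraction_by_group(annotated, verdicts, grouping)
    }
    if (!is.null(config$citation_years)) {
      strata$citations <- citation_comparison(annotated, verdicts,
                                              config$citation_years)
    }
    if ("has_tool_author" %in% names(pubs)) {
      strata$tool_author <- tool_author_split(
        annotated, verdicts, since_year = config$tool_author_since %||% 2017)
    }
    say("stage trends: ", length(strata), " stratification(s) computed")
  }

  summary <- structure(list(
    n_records = nrow(corpus),
    detected = detected,
    prevalence = prevalence,
    strata = strata,
    verdicts = verdicts,
    truth = truth,
    rules = rules,
    source = attr(corpus, "corpus_source"),
    snapshot_date = attr(corpus, "snapshot_date"),
    package_version = as.character(utils::packageVersion("scmetaudit"))
  ), class = "audit_summary")

  if (!is.null(config$out_dir)) {
    write_audit_report(summary, config$out_dir)
    say("stage report: written to ", config$out_dir)
  }
  summary
}

#' @export
print.audit_summary <- function(x, ...) {
  cat("== single-cell metadata deposition audit ==\n")
  cat("source: ", x$source, " (snapshot ", format(x$snapshot_date), "); ",
      x$n_records, " records after merging\n", sep = "")
  print(x$detected)
  if (!is.null(x$prevalence)) print(x$prevalence)
  if (!is.null(x$strata$by_year)) {
    cat("-- fraction with metadata, per year --\n")
    print(x$strata$by_year)
  }
  invisible(x)
}

#' Write an audit summary to report files
#'
#' Emits tab-delimited tables (verdicts, strata) and a Markdown summary.
#' Output is deterministic for a given summary; the only timestamp lives in
#' a dedicated provenance line.
#'
#' @param summary An `audit_summary`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_audit_report <- function(summary, out_dir) {
  stopifnot(inherits(summary, "audit_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- summary$verdicts
  v$matched_rules <- vapply(v$matched, function(m) {
    paste(unique(m$rule), collapse = "|")
  }, character(1))
  readr::write_tsv(v[, c("accession", "positive", "n_matches", "matched_rules")],
                   file.path(out_dir, "verdicts.tsv"))
  for (nm in names(summary$strata)) {
    tbl <- summary$strata[[nm]]
    tbl <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
    readr::write_tsv(tbl, file.path(out_dir, paste0(nm, ".tsv")))
  }
  md <- c(
    "# Cell-level metadata deposition audit",
    "",
    paste0("- source: ", summary$source),
    paste0("- snapshot: ", format(summary$snapshot_date)),
    paste0("- records after merging: ", summary$n_records),
    paste0("- detected fraction: ", summary$detected$n_positive, "/",
           summary$detected$n_records, " = ",
           format(summary$detected$percent, nsmall = 1), "%"),
    if (!is.null(summary$prevalence)) c(
      paste0("- classifier precision: ",
             format(pct1(summary$prevalence$precision), nsmall = 1), "%"),
      paste0("- miss rate among called negatives: ",
             format(pct1(summary$prevalence$miss_rate_among_negatives), nsmall = 1), "%"),
      paste0("- corrected prevalence: ",
             format(summary$prevalence$corrected_percent, nsmall = 1), "% (",
             if (summary$prevalence$within_upper_bound) "within" else "exceeds",
             " the ", summary$prevalence$upper_bound, "% cap)")
    ),
    paste0("- rules: substrings {",
           paste(summary$rules$name_substrings, collapse = ", "),
           "}; extensions {",
           paste(summary$rules$object_extensions, collapse = ", "), "} (",
           summary$rules$extension_mode, " mode)"),
    paste0("- package version: ", summary$package_version),
    paste0("- generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )
  readr::write_lines(unlist(md), file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
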