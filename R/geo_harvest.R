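#' Default single-cell keyword terms
#'
#' The six keyword strings used both inside the repository query and for the
#' post-hoc keyword filter over descriptive fields. GEO has no structured
#' single-cell annotation, so identification rests entirely on these terms.
#'
#' @return Character vector of six terms.
#' @export
geo_keyword_terms <- function() {
  c("single nuclei", "single cell", "scRNAseq", "scRNA-seq",
    "snRNAseq", "snRNA-seq")
}

#' Build the single-cell GEO query
#'
#' Combines the high-throughput expression-profiling dataset-type clause with
#' the OR-disjunction of the six single-cell keywords.
#'
#' @return A list of class `query_spec` with elements `base_expression`,
#'   `keyword_terms` and the assembled `combined` query string.
#' @export
#' @examples
#' build_geo_query()$combined
build_geo_query <- function() {
  base <- "\"expression profiling by high throughput sequencing\""
  terms <- geo_keyword_terms()
  disj <- paste(paste0("\"", terms, "\""), collapse = " OR ")
  structure(
    list(base_expression = base,
         keyword_terms = terms,
         combined = paste0(base, " AND (", disj, ")")),
    class = "query_spec"
  )
}

#' @export
print.query_spec <- function(x, ...) {
  cat("<query_spec>\n", x$combined, "\n", sep = "")
  invisible(x)
}

#' Keyword-filter a record's descriptive fields
#'
#' Retains a record when any term occurs case-insensitively (fixed substring,
#' no regex) in its title, summary, overall design, or library-strategy text.
#'
#' @param record A [repo_record()] or one-row slice of a corpus.
#' @param terms Nonempty character vector of keywords; defaults to
#'   [geo_keyword_terms()].
#' @return `TRUE` to retain, `FALSE` to discard.
#' @export
keyword_filter <- function(record, terms = geo_keyword_terms()) {
  if (length(terms) == 0) stop("terms must be nonempty", call. = FALSE)
  fields <- record_text_fields(record)
  hay <- tolower(paste(fields, collapse = "\n"))
  any(vapply(tolower(terms), function(t) grepl(t, hay, fixed = TRUE),
             logical(1)))
}

record_text_fields <- function(record) {
  pick <- function(f) {
    v <- record[[f]]
    if (is.list(v)) v <- v[[1]]
    if (is.null(v) || length(v) == 0 || is.na(v)) "" else as.character(v)
  }
  c(pick("title"), pick("summary"), pick("overall_design"),
    pick("library_strategy_text"))
}

#' Keyword-filter a whole corpus
#'
#' @param corpus A `record_corpus`.
#' @inheritParams keyword_filter
#' @return The retained subset, still a `record_corpus`.
#' @export
filter_keywords <- function(corpus, terms = geo_keyword_terms()) {
  stopifnot(inherits(corpus, "record_corpus"))
  keep <- vapply(seq_len(nrow(corpus)), function(i) {
    keyword_filter(corpus[i, , drop = FALSE], terms)
  }, logical(1))
  new_record_corpus(tibble::as_tibble(corpus)[keep, , drop = FALSE],
                    snapshot_date = attr(corpus, "snapshot_date"),
                    source = attr(corpus, "corpus_source"))
}

#' Merge SuperSeries families into single records
#'
#' GEO SuperSeries bundle related subseries that describe one study; counting
#' them separately would inflate the denominator and could split a study's
#' metadata file from its matrix. Each family collapses to one record under
#' the superseries accession carrying the union of all supplementary
#' filenames (series- and sample-level kept separate), the earliest
#' submission date, and any PubMed identifier present in the family
#' (superseries' own first, then subseries in ascending accession order).
#' Subseries whose parent is absent from the corpus are promoted to
#' standalone series with a warning. Inconsistent relations (a subseries
#' claiming two parents, or a containment cycle) are errors naming the
#' accessions involved.
#'
#' @param corpus A `record_corpus`.
#' @return A `record_corpus` with no `subseries` rows. The number of merged
#'   families is reported via `message()`.
#' @export
merge_superseries <- function(corpus) {
  stopifnot(inherits(corpus, "record_corpus"))
  tbl <- tibble::as_tibble(corpus)
  is_super <- tbl$record_type == "superseries"
  is_sub <- tbl$record_type == "subseries"
  if (!any(is_super) && !any(is_sub)) return(corpus)

  # parent of every subseries: its own declared parent, or the superseries
  # that lists it as a child
  parent_of <- stats::setNames(rep(NA_character_, nrow(tbl)), tbl$accession)
  for (i in which(is_sub)) {
    parents <- tbl$related_accessions[[i]]
    if (length(unique(parents)) > 1) {
      stop("corpus inconsistency: subseries ", tbl$accession[i],
           " claims multiple parents (", paste(parents, collapse = ", "), ")",
           call. = FALSE)
    }
    if (length(parents) == 1) parent_of[tbl$accession[i]] <- parents
  }
  for (i in which(is_super)) {
    for (child in tbl$related_accessions[[i]]) {
      known <- parent_of[child]
      if (!is.na(child) && child %in% names(parent_of)) {
        if (!is.na(known) && known != tbl$accession[i]) {
          stop("corpus inconsistency: subseries ", child,
               " claimed by both ", known, " and ", tbl$accession[i],
               call. = FALSE)
        }
        parent_of[child] <- tbl$accession[i]
      }
    }
  }
  # cycles: a superseries may not itself be some family's subseries chain
  for (acc in tbl$accession) {
    seen <- character()
    cur <- acc
    while (!is.na(parent_of[cur] %|NA|% NA_character_) &&
           parent_of[cur] %in% tbl$accession) {
      if (parent_of[cur] %in% c(seen, cur)) {
        stop("corpus inconsistency: containment cycle involving ",
             paste(unique(c(seen, cur, parent_of[cur])), collapse = ", "),
             call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- parent_of[cur]
    }
  }

  promoted <- character()
  fam <- tbl$accession
  for (i in which(is_sub)) {
    p <- parent_of[tbl$accession[i]]
    if (is.na(p)) {
      promoted <- c(promoted, tbl$accession[i])
    } else if (!p %in% tbl$accession) {
      promoted <- c(promoted, tbl$accession[i])
    } else {
      fam[i] <- p
    }
  }
  if (length(promoted) > 0) {
    warning("subseries without a retrievable parent promoted to standalone ",
            "records: ", paste(promoted, collapse = ", "), call. = FALSE)
  }

  merged <- lapply(split(seq_len(nrow(tbl)), fam), function(idx) {
    if (length(idx) == 1 && tbl$record_type[idx] != "superseries") {
      r <- corpus_record(corpus, idx)
      if (r$record_type == "subseries") {
        r$record_type <- "series"
        r$related_accessions <- character()
      }
      return(r)
    }
    sup <- idx[tbl$record_type[idx] == "superseries"]
    head_i <- if (length(sup) >= 1) sup[1] else idx[order(tbl$accession[idx])][1]
    dates <- tbl$submission_date[idx]
    pm_order <- idx[order(tbl$record_type[idx] != "superseries", tbl$accession[idx])]
    pmids <- tbl$publication_id[pm_order]
    pmid <- pmids[!is.na(pmids)][1] %|NA|% NA_character_
    repo_record(
      accession = tbl$accession[head_i],
      title = tbl$title[head_i],
      summary = tbl$summary[head_i],
      overall_design = tbl$overall_design[head_i],
      record_type = "series",
      related_accessions = character(),
      supp_series = unlist(tbl$supp_series[idx], use.names = FALSE),
      supp_sample = unlist(tbl$supp_sample[idx], use.names = FALSE),
      submission_date = if (all(is.na(dates))) as.Date(NA) else min(dates, na.rm = TRUE),
      publication_id = if (length(pmid) == 0) NA_character_ else pmid,
      library_strategy_text = tbl$library_strategy_text[head_i]
    )
  })
  n_families <- sum(vapply(split(seq_len(nrow(tbl)), fam), length, integer(1)) > 1)
  if (n_families > 0) message("merged ", n_families, " SuperSeries famil",
                              if (n_families == 1) "y" else "ies")
  out <- record_corpus(unname(merged),
                       snapshot_date = attr(corpus, "snapshot_date"),
                       source = attr(corpus, "corpus_source"))
  new_record_corpus(
    tibble::as_tibble(out)[order(match(out$accession, tbl$accession)), , drop = FALSE],
    snapshot_date = attr(corpus, "snapshot_date"),
    source = attr(corpus, "corpus_source"))
}
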