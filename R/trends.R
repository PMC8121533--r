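#' Join publication information onto a corpus
#'
#' Records with a linked PubMed identifier gain publication year, journal,
#' citation count and tool-author flag; records without a match are flagged
#' `annotated = FALSE` and excluded from publication-stratified summaries
#' (their count is reported via `message()`).
#'
#' @param corpus A `record_corpus` (merged).
#' @param pubs A data frame of publication info with columns
#'   `publication_id`, `year`, `journal`, `citation_count`,
#'   `has_tool_author` (extra columns carried through). `publication_id`
#'   must be unique.
#' @return A tibble: the corpus columns plus the publication columns,
#'   `annotated` (logical) and `audit_year` (publication year when linked,
#'   else the submission year).
#' @export
join_publications <- function(corpus, pubs) {
  stopifnot(inherits(corpus, "record_corpus"))
  pubs <- tibble::as_tibble(pubs)
  needed <- c("publication_id", "year")
  missing_cols <- setdiff(needed, names(pubs))
  if (length(missing_cols) > 0) {
    stop("pubs lacks required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pubs$publication_id)) {
    stop("duplicate publication_id keys in pubs", call. = FALSE)
  }
  pubs$publication_id <- as.character(pubs$publication_id)
  out <- dplyr::left_join(tibble::as_tibble(corpus), pubs, by = "publication_id")
  out$annotated <- !is.na(out$publication_id) & out$publication_id %in% pubs$publication_id
  sub_year <- as.integer(format(out$submission_date, "%Y"))
  out$audit_year <- ifelse(out$annotated & !is.na(out$year), out$year, sub_year)
  n_un <- sum(!out$annotated)
  if (n_un > 0) {
    message(n_un, " record(s) without linked publication info; excluded from ",
            "publication-stratified summaries")
  }
  out
}

check_verdicts <- function(annotated, verdicts) {
  v <- tibble::as_tibble(verdicts)[, c("accession", "positive")]
  missing_acc <- setdiff(annotated$accession, v$accession)
  if (length(missing_acc) > 0) {
    stop("no classifier verdict for record(s): ",
         paste(utils::head(missing_acc, 5), collapse = ", "),
         if (length(missing_acc) > 5) " ..." else "", call. = FALSE)
  }
  dplyr::left_join(annotated, v, by = "accession")
}

summarise_strata <- function(tbl, label_col) {
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data[[label_col]]),
    n_records = dplyr::n(),
    n_positive = sum(.data$positive),
    fraction = .data$n_positive / .data$n_records,
    .groups = "drop"
  )
  names(out)[1] <- "stratum_label"
  out
}

#' Metadata-presence fraction per publication year
#'
#' @param annotated Output of [join_publications()].
#' @param verdicts Output of [classify_corpus()] (every record must have a
#'   verdict).
#' @return A tibble with one row per year (ascending): `stratum_label`
#'   (year), `n_records`, `n_positive`, `fraction`. Years with zero records
#'   are omitted; only publication-annotated records are counted.
#' @export
fraction_by_year <- function(annotated, verdicts) {
  tbl <- check_verdicts(annotated, verdicts)
  tbl <- tbl[tbl$annotated & !is.na(tbl$audit_year), , drop = FALSE]
  out <- summarise_strata(dplyr::mutate(tbl, .year = as.integer(.data$audit_year)),
                          ".year")
  dplyr::arrange(out, .data$stratum_label)
}

#' Metadata-presence fraction per journal group
#'
#' Journals absent from the supplied mapping fall into an `"other"` stratum.
#' The shipped example mapping (`inst/extdata/journal_groups.tsv`) is
#' illustrative only — real audits must supply their own grouping.
#'
#' @inheritParams fraction_by_year
#' @param grouping A named character vector (`journal -> group`) or a
#'   two-column data frame (`journal`, `group`).
#' @return A tibble per group: `stratum_label`, `n_records`, `n_positive`,
#'   `fraction`, `share_of_total`.
#' @export
fraction_by_group <- function(annotated, verdicts, grouping) {
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(as.character(grouping[[2]]),
                                as.character(grouping[[1]]))
  }
  tbl <- check_verdicts(annotated, verdicts)
  tbl <- tbl[tbl$annotated, , drop = FALSE]
  if (!"journal" %in% names(tbl)) {
    stop("annotated corpus lacks a 'journal' column", call. = FALSE)
  }
  grp <- unname(grouping[tbl$journal])
  grp[is.na(grp)] <- "other"
  out <- summarise_strata(dplyr::mutate(tbl, .group = grp), ".group")
  out$share_of_total <- out$n_records / sum(out$n_records)
  dplyr::arrange(out, dplyr::desc(.data$n_records))
}

#' Citation distributions by metadata status, per year
#'
#' For each requested publication year, returns the citation-count
#' distributions of metadata-positive and metadata-negative records and
#' their medians. Citation counts are heavy-tailed, so the median is the
#' summary; no hypothesis test is performed or implied.
#'
#' @inheritParams fraction_by_year
#' @param years Integer vector of publication years to compare.
#' @return A tibble with one row per (year, arm): `year`,
#'   `metadata` (logical arm), `n`, `median_citations` (`NA` marks an empty
#'   arm), `citations` (list-column of the raw counts).
#' @export
citation_comparison <- function(annotated, verdicts, years) {
  tbl <- check_verdicts(annotated, verdicts)
  tbl <- tbl[tbl$annotated & !is.na(tbl$audit_year), , drop = FALSE]
  if (!"citation_count" %in% names(tbl)) {
    stop("annotated corpus lacks a 'citation_count' column", call. = FALSE)
  }
  grid <- tidyr::expand_grid(year = as.integer(years),
                             metadata = c(TRUE, FALSE))
  rows <- purrr::pmap(grid, function(year, metadata) {
    cc <- tbl$citation_count[tbl$audit_year == year & tbl$positive == metadata]
    cc <- cc[!is.na(cc)]
    tibble::tibble(
      year = year, metadata = metadata, n = length(cc),
      median_citations = if (length(cc) == 0) NA_real_ else stats::median(cc),
      citations = list(cc)
    )
  })
  dplyr::bind_rows(rows)
}

#' Metadata-presence fraction by tool-author status
#'
#' Splits records from `since_year` onward by whether an author previously
#' published a single-cell software tool (tools typically require cell-level
#' metadata, so their authors are expected to deposit it more often).
#'
#' @inheritParams fraction_by_year
#' @param since_year First publication year included (default 2017).
#' @return A tibble with up to two rows (`tool_author`, `other`):
#'   `stratum_label`, `n_records`, `n_positive`, `fraction`. Strata with no
#'   records are kept with zero counts and `NA` fraction.
#' @export
tool_author_split <- function(annotated, verdicts, since_year = 2017) {
  tbl <- check_verdicts(annotated, verdicts)
  tbl <- tbl[tbl$annotated & !is.na(tbl$audit_year) &
               tbl$audit_year >= since_year, , drop = FALSE]
  if (nrow(tbl) > 0 && !"has_tool_author" %in% names(tbl)) {
    stop("annotated corpus lacks a 'has_tool_author' column", call. = FALSE)
  }
  lab <- function(flag) if (flag) "tool_author" else "other"
  out <- tibble::tibble(stratum_label = c("tool_author", "other"),
                        n_records = 0L, n_positive = 0L, fraction = NA_real_)
  if (nrow(tbl) > 0) {
    got <- summarise_strata(
      dplyr::mutate(tbl, .ta = vapply(.data$has_tool_author, lab, character(1))),
      ".ta")
    out <- dplyr::rows_update(out, got, by = "stratum_label")
  }
  out
}
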