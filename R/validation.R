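#' Manual spot-check contingency counts
#'
#' Tallies from a manual inspection of randomly selected records that the
#' classifier had flagged as single-cell datasets: how many truly were
#' single-cell, how many of those the filename classifier called positive,
#' how many called positives truly deposited cell-level metadata, how many
#' called negatives deposited metadata the filename rules missed, and how
#' many true positives contained named cell types (as opposed to bare
#' cluster labels).
#'
#' @param n_inspected Records manually inspected.
#' @param n_true_single_cell Those confirmed as single-cell (others were
#'   different modalities, e.g. bulk RNA-seq, caught by the keyword query).
#' @param n_called_positive Classifier positives among the true single-cell
#'   records.
#' @param n_true_positive Called positives that truly contained cell-level
#'   metadata.
#' @param n_missed_with_metadata Called negatives that contained metadata.
#' @param n_with_cell_type Called positives with actual cell-type labels
#'   (optional; `NA` when not tallied).
#' @return A list of class `validation_counts`.
#' @export
#' @examples
#' validation_counts(173, 156, 27, 24, 10, 22)
validation_counts <- function(n_inspected, n_true_single_cell,
                              n_called_positive, n_true_positive,
                              n_missed_with_metadata,
                              n_with_cell_type = NA_integer_) {
  counts <- list(
    n_inspected = as.integer(n_inspected),
    n_true_single_cell = as.integer(n_true_single_cell),
    n_called_positive = as.integer(n_called_positive),
    n_true_positive = as.integer(n_true_positive),
    n_missed_with_metadata = as.integer(n_missed_with_metadata),
    n_with_cell_type = as.integer(n_with_cell_type)
  )
  with(counts, {
    if (n_true_single_cell > n_inspected) {
      stop("n_true_single_cell exceeds n_inspected", call. = FALSE)
    }
    if (n_called_positive > n_true_single_cell) {
      stop("n_called_positive exceeds n_true_single_cell", call. = FALSE)
    }
    if (n_true_positive > n_called_positive) {
      stop("n_true_positive exceeds n_called_positive", call. = FALSE)
    }
    if (n_missed_with_metadata > n_true_single_cell - n_called_positive) {
      stop("n_missed_with_metadata exceeds the number of called negatives",
           call. = FALSE)
    }
  })
  structure(counts, class = "validation_counts")
}

#' @export
print.validation_counts <- function(x, ...) {
  cat("<validation_counts> inspected ", x$n_inspected,
      "; true single-cell ", x$n_true_single_cell,
      "; called positive ", x$n_called_positive,
      " (true positive ", x$n_true_positive,
      "); missed with metadata ", x$n_missed_with_metadata, "\n", sep = "")
  invisible(x)
}

#' Read spot-check counts from a tab-delimited file
#'
#' Expects a two-column `field<TAB>value` table (or a one-row table with the
#' field names as header) using the argument names of [validation_counts()].
#'
#' @param path File path.
#' @return A [validation_counts()] object.
#' @export
read_validation_counts <- function(path) {
  tbl <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tbl) == 2 && !"n_inspected" %in% names(tbl)) {
    vals <- stats::setNames(as.integer(tbl[[2]]), tbl[[1]])
  } else {
    vals <- stats::setNames(as.integer(tbl[1, ]), names(tbl))
  }
  validation_counts(
    n_inspected = vals[["n_inspected"]],
    n_true_single_cell = vals[["n_true_single_cell"]],
    n_called_positive = vals[["n_called_positive"]],
    n_true_positive = vals[["n_true_positive"]],
    n_missed_with_metadata = vals[["n_missed_with_metadata"]],
    n_with_cell_type = if ("n_with_cell_type" %in% names(vals))
      vals[["n_with_cell_type"]] else NA_integer_
  )
}

pct1 <- function(x) round(100 * x, 1)  # round-half-even, one decimal

#' Classifier precision from spot-check counts
#'
#' Percentage of called-positive records that truly deposited cell-level
#' metadata.
#'
#' @param counts A [validation_counts()] object.
#' @return Percentage, rounded half-even to one decimal.
#' @export
#' @examples
#' precision(validation_counts(173, 156, 27, 24, 10))  # 88.9
precision <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  if (counts$n_called_positive <= 0) {
    stop("undefined ratio: no called-positive records", call. = FALSE)
  }
  pct1(counts$n_true_positive / counts$n_called_positive)
}

#' Missed-metadata rate among true single-cell records
#'
#' Percentage of true single-cell records whose metadata files the filename
#' rules missed, with the full true-single-cell count as denominator (the
#' rate conventionally printed alongside the precision). The rate among
#' called negatives, which the prevalence correction uses, is
#' `miss_rate_among_negatives` in [corrected_prevalence()].
#'
#' @inheritParams precision
#' @return Percentage, one decimal.
#' @export
missed_metadata_rate <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  if (counts$n_true_single_cell <= 0) {
    stop("undefined ratio: no true single-cell records", call. = FALSE)
  }
  pct1(counts$n_missed_with_metadata / counts$n_true_single_cell)
}

#' Other-modality contamination among keyword-identified records
#'
#' Percentage of inspected records that were not single-cell at all (e.g.
#' bulk RNA-seq swept up by the keyword query).
#'
#' @inheritParams precision
#' @return Percentage, one decimal.
#' @export
other_modality_fraction <- function(counts) {
  stopifnot(inherits(counts, "validation_counts"))
  if (counts$n_inspected <= 0) {
    stop("undefined ratio: no inspected records", call. = FALSE)
  }
  pct1((counts$n_inspected - counts$n_true_single_cell) / counts$n_inspected)
}

#' Misclassification-corrected prevalence of metadata deposition
#'
#' Adjusts the raw detected rate `d` for both classifier error modes
#' measured in the spot check: false positives (via the precision
#' `p = n_true_positive / n_called_positive`) and missed metadata files (via
#' the miss rate among called negatives,
#' `m = n_missed_with_metadata / (n_true_single_cell - n_called_positive)`).
#' The corrected estimate is the standard misclassification adjustment
#'
#'   `corrected = d * p + (1 - d) * m`
#'
#' i.e. the expected fraction of records that truly deposit metadata given
#' how often calls in each arm turn out to be right. All components are
#' returned so alternative corrections can be applied.
#'
#' @param detected_rate Corpus-level detected fraction `d`, in `[0, 1]`.
#' @param counts A [validation_counts()] object.
#' @param upper_bound Headline cap, in percent, against which the corrected
#'   estimate is checked (default 25).
#' @return A list of class `prevalence_estimate` with `detected_rate`,
#'   `precision`, `miss_rate_among_negatives`, `corrected` (proportion),
#'   `corrected_percent` (one decimal), `upper_bound`, and
#'   `within_upper_bound`.
#' @export
#' @examples
#' corrected_prevalence(0.135, validation_counts(173, 156, 27, 24, 10))
corrected_prevalence <- function(detected_rate, counts, upper_bound = 25) {
  stopifnot(inherits(counts, "validation_counts"))
  if (is.na(detected_rate) || detected_rate < 0 || detected_rate > 1) {
    stop("detected_rate must lie in [0, 1]", call. = FALSE)
  }
  if (counts$n_called_positive <= 0) {
    stop("undefined ratio: no called-positive records", call. = FALSE)
  }
  n_neg <- counts$n_true_single_cell - counts$n_called_positive
  if (n_neg <= 0) {
    stop("undefined ratio: no called-negative records", call. = FALSE)
  }
  p <- counts$n_true_positive / counts$n_called_positive
  m <- counts$n_missed_with_metadata / n_neg
  corrected <- detected_rate * p + (1 - detected_rate) * m
  structure(list(
    detected_rate = detected_rate,
    precision = p,
    miss_rate_among_negatives = m,
    corrected = corrected,
    corrected_percent = pct1(corrected),
    upper_bound = upper_bound,
    within_upper_bound = pct1(corrected) <= upper_bound
  ), class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat("<prevalence_estimate>\n",
      "  detected rate d        : ", format(pct1(x$detected_rate), nsmall = 1), "%\n",
      "  precision p            : ", format(pct1(x$precision), nsmall = 1), "%\n",
      "  miss rate (negatives) m: ", format(pct1(x$miss_rate_among_negatives), nsmall = 1), "%\n",
      "  corrected d*p + (1-d)*m: ", format(x$corrected_percent, nsmall = 1), "%",
      " (", if (x$within_upper_bound) "within" else "EXCEEDS",
      " the ", x$upper_bound, "% cap)\n", sep = "")
  invisible(x)
}
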