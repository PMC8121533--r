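#' Load a count matrix + cell-metadata bundle
#'
#' Reads the two processed files that make a single-cell deposition minimally
#' replicable — the gene-by-cell count matrix and the cell-level metadata
#' table — without touching the expression values beyond an integrality
#' check. Cell identifiers are taken verbatim (no barcode normalization at
#' load time). Metadata column roles are inferred from the header: names
#' containing "type", "cluster" or "annot" (case-insensitive) are flagged as
#' cell-type/cluster annotation; names following UMAP/tSNE/PCA coordinate
#' conventions as embedding coordinates.
#'
#' @param matrix_path Count matrix file: a MatrixMarket triplet (`.mtx`) or
#'   a dense delimited table with gene identifiers in the first column and
#'   cell identifiers as the header.
#' @param metadata_path Delimited cell-metadata table; the cell identifier
#'   is taken from a column named like `cell`/`barcode` when present, else
#'   from the first column.
#' @param matrix_format `"mtx_triplet"` or `"dense_delimited"`.
#' @param barcodes_path,features_path Companion identifier files (one per
#'   line; first tab-delimited field used), required for `mtx_triplet`.
#' @return A list of class `deposit_bundle`: `matrix_cell_ids`, `gene_ids`,
#'   `counts_present` (TRUE iff all parsed values are nonnegative integers),
#'   `metadata_cell_ids`, `metadata_columns` (tibble of column/role).
#' @export
load_bundle <- function(matrix_path, metadata_path,
                        matrix_format = c("mtx_triplet", "dense_delimited"),
                        barcodes_path = NULL, features_path = NULL) {
  matrix_format <- match.arg(matrix_format)
  for (p in c(matrix_path, metadata_path)) {
    if (!file.exists(p)) stop("cannot read '", p, "'", call. = FALSE)
  }
  if (matrix_format == "mtx_triplet") {
    if (is.null(barcodes_path) || is.null(features_path)) {
      stop("mtx_triplet format requires barcodes_path and features_path",
           call. = FALSE)
    }
    m <- Matrix::readMM(matrix_path)
    read_ids <- function(p) {
      vapply(strsplit(readr::read_lines(p), "\t", fixed = TRUE),
             `[[`, character(1), 1)
    }
    barcodes <- read_ids(barcodes_path)
    features <- read_ids(features_path)
    if (length(barcodes) != ncol(m)) {
      stop("dimension mismatch: ", length(barcodes), " barcodes for ",
           ncol(m), " matrix columns", call. = FALSE)
    }
    if (length(features) != nrow(m)) {
      stop("dimension mismatch: ", length(features), " features for ",
           nrow(m), " matrix rows", call. = FALSE)
    }
    values <- m@x
  } else {
    tbl <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                             sep = guess_sep(matrix_path),
                             stringsAsFactors = FALSE)
    features <- as.character(tbl[[1]])
    barcodes <- names(tbl)[-1]
    values <- unlist(tbl[-1], use.names = FALSE)
    values <- suppressWarnings(as.numeric(values))
  }
  counts_present <- length(values) > 0 &&
    !anyNA(values) && all(values >= 0) && all(values == floor(values))
  if (!counts_present) {
    warning("count-integrity check failed: matrix holds negative, missing ",
            "or non-integer values", call. = FALSE)
  }

  meta <- utils::read.delim(metadata_path, header = TRUE, check.names = FALSE,
                            sep = guess_sep(metadata_path),
                            stringsAsFactors = FALSE)
  id_col <- grep("^(cell([_. -]?(id|barcode|name))?|barcode)s?$",
                 names(meta), ignore.case = TRUE)
  id_col <- if (length(id_col) > 0) id_col[1] else 1L
  metadata_cell_ids <- as.character(meta[[id_col]])
  roles <- vapply(names(meta), infer_column_role, character(1))
  structure(list(
    matrix_cell_ids = barcodes,
    gene_ids = features,
    counts_present = counts_present,
    metadata_cell_ids = metadata_cell_ids,
    metadata_columns = tibble::tibble(column = names(meta),
                                      role = unname(roles))
  ), class = "deposit_bundle")
}

guess_sep <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

infer_column_role <- function(name) {
  n <- tolower(name)
  if (grepl("type|cluster|annot", n)) return("cell_type_or_cluster")
  if (grepl("^(umap|tsne|t-sne|pc|pca)[_. -]?[0-9]+$", n) ||
      grepl("^(x|y)_(umap|tsne|pca)$", n)) {
    return("embedding_coordinate")
  }
  "other"
}

#' @export
print.deposit_bundle <- function(x, ...) {
  cat("<deposit_bundle> ", length(x$gene_ids), " genes x ",
      length(x$matrix_cell_ids), " cells; metadata rows: ",
      length(x$metadata_cell_ids), "\n", sep = "")
  print(x$metadata_columns)
  invisible(x)
}

#' Check count-matrix / metadata identifier concordance
#'
#' The minimal replication standard asks that the metadata table cover
#' exactly the cell identifiers present in the count matrix and carry a
#' cell-type or cluster annotation column. The verdict is `"compliant"` when
#' the identifier sets match exactly and such a column exists, `"partial"`
#' when at least one identifier matches, and `"noncompliant"` when the sets
#' are disjoint.
#'
#' @param bundle A [load_bundle()] result.
#' @param barcode_normalization `"none"` (default; identifiers compared
#'   verbatim) or `"strip_suffix"` (drop a trailing `-<digits>` 10x-style
#'   suffix from both sides before comparing).
#' @return A list of class `concordance_report`: `n_matched`,
#'   `n_matrix_only`, `n_metadata_only`, `has_celltype_column`,
#'   `has_embedding`, `verdict`.
#' @export
concordance <- function(bundle,
                        barcode_normalization = c("none", "strip_suffix")) {
  stopifnot(inherits(bundle, "deposit_bundle"))
  barcode_normalization <- match.arg(barcode_normalization)
  norm <- function(x) {
    if (barcode_normalization == "strip_suffix") sub("-[0-9]+$", "", x) else x
  }
  mx <- unique(norm(bundle$matrix_cell_ids))
  md <- unique(norm(bundle$metadata_cell_ids))
  n_matched <- length(intersect(mx, md))
  n_matrix_only <- length(setdiff(mx, md))
  n_metadata_only <- length(setdiff(md, mx))
  has_celltype <- any(bundle$metadata_columns$role == "cell_type_or_cluster")
  has_embedding <- any(bundle$metadata_columns$role == "embedding_coordinate")
  verdict <- if (n_matched == 0) "noncompliant"
             else if (n_matrix_only == 0 && n_metadata_only == 0 && has_celltype) "compliant"
             else "partial"
  structure(list(
    n_matched = n_matched,
    n_matrix_only = n_matrix_only,
    n_metadata_only = n_metadata_only,
    has_celltype_column = has_celltype,
    has_embedding = has_embedding,
    verdict = verdict
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> verdict: ", x$verdict, "\n",
      "  matched cells      : ", x$n_matched, "\n",
      "  matrix-only cells  : ", x$n_matrix_only, "\n",
      "  metadata-only cells: ", x$n_metadata_only, "\n",
      "  cell-type column   : ", x$has_celltype_column, "\n",
      "  embedding columns  : ", x$has_embedding, "\n", sep = "")
  invisible(x)
}
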