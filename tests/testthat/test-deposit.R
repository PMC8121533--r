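demo_bundle <- function() {
  load_bundle(extdata("demo_bundle", "matrix.mtx"),
              extdata("demo_bundle", "cell_metadata.tsv"),
              matrix_format = "mtx_triplet",
              barcodes_path = extdata("demo_bundle", "barcodes.tsv"),
              features_path = extdata("demo_bundle", "features.tsv"))
}

write_meta <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("an MTX triplet bundle loads with inferred column roles", {
  b <- demo_bundle()
  expect_equal(b$matrix_cell_ids, c("AAACCTGA-1", "AAACGGGT-1", "AAAGATGC-1"))
  expect_length(b$gene_ids, 4)
  expect_true(b$counts_present)
  roles <- setNames(b$metadata_columns$role, b$metadata_columns$column)
  expect_equal(unname(roles["cell_type"]), "cell_type_or_cluster")
  expect_equal(unname(roles["cluster"]), "cell_type_or_cluster")
  expect_equal(unname(roles[c("UMAP_1", "UMAP_2")]),
               rep("embedding_coordinate", 2))
})

test_that("identifier files of the wrong length are dimension errors", {
  short <- write_meta(c("AAACCTGA-1", "AAACGGGT-1"))
  expect_error(
    load_bundle(extdata("demo_bundle", "matrix.mtx"),
                extdata("demo_bundle", "cell_metadata.tsv"),
                "mtx_triplet", barcodes_path = short,
                features_path = extdata("demo_bundle", "features.tsv")),
    "dimension mismatch")
})

test_that("dense matrices parse and non-integer values void counts_present", {
  dense <- write_meta(c("gene\tC1\tC2", "G1\t3\t0", "G2\t1\t7"))
  meta <- write_meta(c("cell\tcell_type", "C1\tb_cell", "C2\tt_cell"))
  b <- load_bundle(dense, meta, "dense_delimited")
  expect_true(b$counts_present)
  expect_equal(b$matrix_cell_ids, c("C1", "C2"))
  real <- write_meta(c("gene\tC1\tC2", "G1\t3.5\t0", "G2\t1\t7"))
  expect_warning(b2 <- load_bundle(real, meta, "dense_delimited"),
                 "count-integrity")
  expect_false(b2$counts_present)
})

test_that("identical identifier sets with a cell-type column are compliant", {
  rep <- concordance(demo_bundle())
  expect_equal(rep$verdict, "compliant")
  expect_equal(rep$n_matched, 3)
  expect_equal(rep$n_matrix_only, 0)
  expect_equal(rep$n_metadata_only, 0)
  expect_true(rep$has_celltype_column)
  expect_true(rep$has_embedding)
})

test_that("partial and disjoint identifier sets grade accordingly", {
  meta2 <- write_meta(c("cell\tcell_type",
                        "AAACCTGA-1\tb_cell", "AAACGGGT-1\tmelanoma"))
  b <- load_bundle(extdata("demo_bundle", "matrix.mtx"), meta2,
                   "mtx_triplet",
                   barcodes_path = extdata("demo_bundle", "barcodes.tsv"),
                   features_path = extdata("demo_bundle", "features.tsv"))
  rep <- concordance(b)
  expect_equal(rep$verdict, "partial")
  expect_equal(rep$n_matrix_only, 1)
  expect_equal(rep$n_matched, 2)

  disjoint <- write_meta(c("cell\tcell_type", "XXX\tb_cell"))
  b2 <- load_bundle(extdata("demo_bundle", "matrix.mtx"), disjoint,
                    "mtx_triplet",
                    barcodes_path = extdata("demo_bundle", "barcodes.tsv"),
                    features_path = extdata("demo_bundle", "features.tsv"))
  expect_equal(concordance(b2)$verdict, "noncompliant")
})

test_that("suffix stripping reconciles 10x-style barcodes", {
  bare <- write_meta(c("cell\tcell_type", "AAACCTGA\tb_cell",
                       "AAACGGGT\tmelanoma", "AAAGATGC\tmyeloid"))
  b <- load_bundle(extdata("demo_bundle", "matrix.mtx"), bare,
                   "mtx_triplet",
                   barcodes_path = extdata("demo_bundle", "barcodes.tsv"),
                   features_path = extdata("demo_bundle", "features.tsv"))
  expect_equal(concordance(b, "none")$n_matched, 0)
  rep <- concordance(b, "strip_suffix")
  expect_equal(rep$n_matched, 3)
  expect_equal(rep$verdict, "compliant")
})

test_that("report partition equalities hold on every fixture (property)", {
  metas <- list(
    c("cell\tcell_type", "AAACCTGA-1\tb_cell"),
    c("cell\tcell_type", "AAACCTGA-1\tb_cell", "ZZZ-1\tmelanoma"),
    c("cell\tnote", "AAACCTGA-1\tx", "AAACGGGT-1\ty", "AAAGATGC-1\tz")
  )
  for (lines in metas) {
    meta <- write_meta(lines)
    b <- load_bundle(extdata("demo_bundle", "matrix.mtx"), meta,
                     "mtx_triplet",
                     barcodes_path = extdata("demo_bundle", "barcodes.tsv"),
                     features_path = extdata("demo_bundle", "features.tsv"))
    rep <- concordance(b)
    expect_equal(rep$n_matched + rep$n_matrix_only, length(b$matrix_cell_ids))
    expect_equal(rep$n_matched + rep$n_metadata_only, length(b$metadata_cell_ids))
  }
})
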