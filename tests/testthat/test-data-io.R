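test_that("MTX round trip reproduces counts, ids and metadata exactly", {
  counts <- count_matrix(4, 5, lambda = 2)
  ds <- make_ds(counts, cluster = c("A", "A", "B", "B"),
                condition = c("tumor", "control", "tumor", "control"),
                donor = "D1", compartment = "CD8")
  dir <- tempfile("mtx_")
  write_dataset(ds, dir)
  ds2 <- load_counts(dir, "mtx_dir")
  meta <- read.delim(file.path(dir, "cell_meta.tsv"), stringsAsFactors = FALSE)
  ds2 <- attach_metadata(ds2, meta)
  expect_identical(dim(ds2$counts), dim(ds$counts))
  expect_equal(ds2$counts, ds$counts)
  expect_identical(rownames(ds2$counts), rownames(ds$counts))
  expect_identical(ds2$cell_meta$cluster, ds$cell_meta$cluster)
  expect_identical(ds2$cell_meta$condition, ds$cell_meta$condition)
})

test_that("small MTX triplet reads back with the stored nonzeros", {
  dir <- tempfile("mtx_")
  dir.create(dir)
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 4, 1), j = c(1, 1, 2, 3, 3),
                            x = c(1, 2, 3, 4, 5), dims = c(4, 3))  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(paste0("G", 1:4, "\tG", 1:4), file.path(dir, "features.tsv"))
  writeLines(paste0("BC", 1:3), file.path(dir, "barcodes.tsv"))
  ds <- load_counts(dir, "mtx_dir")
  expect_identical(dim(ds$counts), c(3L, 4L))
  expect_identical(sum(ds$counts > 0), 5L)
  expect_identical(ds$counts["BC3", "G1"], 5)
})

test_that("duplicate gene symbols are deduplicated with 10x-style suffixes", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "GZMB\t1\t0", "GZMB\t2\t3", "PRF1\t0\t1"), tsv)
  expect_warning(ds <- load_counts(tsv, "dense_tsv"), "dedup")
  expect_identical(colnames(ds$counts), c("GZMB", "GZMB-1", "PRF1"))
})

test_that("degenerate inputs raise format errors naming the problem", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("gene\tc1", tsv)
  expect_error(load_counts(tsv, "dense_tsv"), "empty")
  dir <- tempfile("mtx_")
  dir.create(dir)
  m <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 2))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  expect_error(load_counts(dir, "mtx_dir"), "features.tsv")
  expect_error(expression_dataset(matrix(c(0.5, 1, 1, 1), 2)), "integer")
})

test_that("10x contig dialect parses with the documented truth strings", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "barcode,chain,v_gene,j_gene,cdr3_nt,cdr3,productive,umis",
    "AAAC-1,TRB,TRBV2,TRBJ1,TGTGCA,CA,true,7",
    "AAAC-1,TRA,TRAV3,TRAJ2,TGTGCC,CA,None,2",
    "AAAG-1,TRB,TRBV2,TRBJ1,TGTGCA,CA,false,3"), csv)
  ct <- load_contigs(csv, "tenx_csv")
  expect_s3_class(ct, "ContigTable")
  expect_identical(nrow(ct), 3L)
  expect_identical(ct$productive, c(TRUE, FALSE, FALSE))
  expect_identical(attr(ct, "dropped_loci"), 0L)
})

test_that("AIRR dialect drops non-TRA/TRB loci with a counted warning", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("cell_id", "locus", "v_call", "j_call", "junction", "junction_aa",
          "productive", "duplicate_count", sep = "\t"),
    paste("c1", "TRB", "TRBV1", "TRBJ1", "TGTGCA", "CA", "T", 4, sep = "\t"),
    paste("c1", "TRG", "TRGV1", "TRGJ1", "TGTGCA", "CA", "T", 2, sep = "\t")), tsv)
  expect_warning(ct <- load_contigs(tsv, "airr_tsv"), "non-TRA/TRB")
  expect_identical(nrow(ct), 1L)
  expect_identical(attr(ct, "dropped_loci"), 1L)
  # row accounting: kept + dropped = input rows
  expect_identical(nrow(ct) + attr(ct, "dropped_loci"), 2L)
  expect_error(load_contigs(tsv, "bogus"))
})

test_that("metadata attachment honors strict mode and rejects duplicates", {
  ds <- make_ds(count_matrix(3, 2))
  meta <- data.frame(cell_id = c("c001", "c002", "c003"),
                     cluster = c("A", "A", "B"))
  ds2 <- attach_metadata(ds, meta)
  expect_identical(ds2$cell_meta$cluster, c("A", "A", "B"))
  expect_error(attach_metadata(ds, meta[1:2, ], strict = TRUE), "c003")
  expect_warning(attach_metadata(ds, rbind(meta, data.frame(cell_id = "zzz", cluster = "C"))),
                 "zzz")
  expect_error(attach_metadata(ds, meta[c(1, 1, 2), ]), "duplicate")
})

test_that("GMT files round trip", {
  sets <- gene_set_collection(list(a = c("X", "Y"), b = "Z"),
                              provenance = c(a = "p1", b = "p2"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(back$a, c("X", "Y"))
  expect_identical(attr(back, "provenance")[["b"]], "p2")
  expect_error(gene_set_collection(list(a = character(0))), "empty")
})
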