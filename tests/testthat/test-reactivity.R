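toy_index_table <- function(enrich, expans, prolif, z, insufficient = FALSE) {
  idx <- data.frame(cluster = paste0("K", seq_along(enrich)),
                    n_cells = 100L, n_tumor_cells = 50L,
                    tumor_enrichment_index = enrich,
                    clonal_expansion_index = expans,
                    proliferation_index = prolif,
                    z_s1 = z,
                    insufficient = insufficient,
                    stringsAsFactors = FALSE)
  class(idx) <- c("ClusterIndexTable", "data.frame")
  idx
}

test_that("cluster indices reproduce hand values on a two-cluster toy", {
  n <- 100
  cluster <- rep(c("A", "B"), c(25, 75))
  condition <- c(rep("tumor", 25), rep(c("tumor", "control"), c(25, 50)))
  counts <- count_matrix(n, 6, lambda = 1, seed = 9)
  colnames(counts) <- paste0("g", 1:6)
  counts[, "g1"] <- rep(c(1L, 0L), c(25, 75))  # proliferation only in A
  ds <- make_ds(counts, cluster = cluster, condition = condition)
  ds <- normalize_log1p(ds)
  tumor_cells <- rownames(counts)[condition == "tumor"]
  df <- do.call(rbind, Map(paired_contigs, tumor_cells,
                           sprintf("A%02d", seq_along(tumor_cells))))
  assign <- call_clonotypes(contig_table(df))
  idx <- compute_cluster_indices(
    ds, assign,
    signaling_sets = gene_set_collection(list(s1 = c("g2", "g3"))),
    proliferation_genes = "g1", min_tumor_cells = 20, n_bins = 1, seed = 1)
  expect_equal(idx$tumor_enrichment_index[idx$cluster == "A"], 2.0,
               tolerance = 1e-12)
  expect_equal(idx$tumor_enrichment_index[idx$cluster == "B"], 2 / 3,
               tolerance = 1e-12)
  # all-singleton clonotypes -> expansion 0 in both clusters
  expect_equal(idx$clonal_expansion_index, c(0, 0), tolerance = 1e-12)
  expect_equal(idx$proliferation_index, c(1, 0))
  # z-scores have mean zero across clusters
  expect_equal(mean(idx$z_s1), 0, tolerance = 1e-9)
})

test_that("constant expression gives all-zero signaling z-scores", {
  counts <- matrix(3L, 60, 4, dimnames = list(sprintf("c%02d", 1:60), paste0("g", 1:4)))
  counts[, "g1"] <- 1L
  ds <- make_ds(counts, cluster = rep(c("A", "B"), 30),
                condition = rep("tumor", 60), normalize = TRUE)
  cells <- rownames(counts)
  df <- do.call(rbind, Map(paired_contigs, cells, sprintf("A%02d", seq_along(cells))))
  idx <- compute_cluster_indices(
    ds, call_clonotypes(contig_table(df)),
    signaling_sets = gene_set_collection(list(s1 = c("g2", "g3"))),
    proliferation_genes = "g1", min_tumor_cells = 10, n_bins = 1, seed = 1)
  expect_equal(idx$z_s1, c(0, 0))
})

test_that("pTRT calling applies the stated comparison operators at the boundary", {
  idx <- toy_index_table(enrich = c(1.2, 2.0, 0.4),
                         expans = c(0.2, 0.6, 0.6),
                         prolif = c(0.05, 0.2, 0.2),
                         z = c(0.001, 1.1, 1.1))
  called <- call_ptrt_clusters(idx)
  # >= for the three indices, strict > for the signaling median
  expect_identical(called$is_ptrt, c(TRUE, TRUE, FALSE))
  idx0 <- toy_index_table(1.2, 0.2, 0.05, 0)
  expect_warning(c0 <- call_ptrt_clusters(idx0), "no cluster")
  expect_false(c0$is_ptrt)
  # insufficient clusters are never called
  idx2 <- toy_index_table(2, 0.6, 0.2, 1.1, insufficient = TRUE)
  expect_warning(c2 <- call_ptrt_clusters(idx2), "no cluster")
  expect_false(c2$is_ptrt)
})

test_that("raising any threshold never enlarges the pTRT set", {
  for (i in 1:20) {
    idx <- with_fixed_seed(4000 + i,
      toy_index_table(enrich = runif(6, 0, 3), expans = runif(6),
                      prolif = runif(6, 0, 0.5), z = rnorm(6)))
    base <- suppressWarnings(call_ptrt_clusters(idx, 1.0, 0.1, 0.02, -0.5))
    for (j in 1:5) {
      taus <- with_fixed_seed(5000 + 10 * i + j,
                              c(1.0, 0.1, 0.02, -0.5) + runif(4, 0, 1))
      up <- suppressWarnings(call_ptrt_clusters(idx, taus[1], taus[2], taus[3], taus[4]))
      expect_true(all(idx$cluster[up$is_ptrt] %in% idx$cluster[base$is_ptrt]))
    }
  }
})

test_that("reactivity labels follow the cluster/sharing rules and partition cells", {
  cells <- paste0("c", 1:6)
  clusters <- c("P", "P", "Q", "Q", "R", "R")
  clones <- c("AA", "BB", "AA", "CC", "DD", "EE")
  # c6 has no TCR at all
  df <- do.call(rbind, Map(paired_contigs, cells[1:5], clones[1:5]))
  df <- rbind(df, contig_row("c6", "TRB"))
  counts <- count_matrix(6, 3)
  rownames(counts) <- cells
  ds <- make_ds(counts, cluster = clusters, condition = rep("tumor", 6))
  assign <- call_clonotypes(contig_table(df))
  lab <- label_reactivity(ds, assign, "P")
  expect_identical(unname(unclass(lab)),
                   c("pTRT", "pTRT", "pTRT-relevant", "pTRT-irrelevant",
                     "pTRT-irrelevant", "pTRT-irrelevant"))
  # partition identity
  expect_identical(length(lab), 6L)
  expect_identical(sum(table(unclass(lab))), 6L)
  comp <- relevant_composition(lab, setNames(clusters, cells))
  expect_equal(as.numeric(comp[c("P", "Q", "R")]), c(0, 0.5, 0))
})

test_that("adding a bystander cell with a fresh clonotype changes no other label", {
  cells <- paste0("c", 1:5)
  clusters <- c("P", "P", "Q", "Q", "R")
  clones <- c("AA", "BB", "AA", "CC", "DD")
  df <- do.call(rbind, Map(paired_contigs, cells, clones))
  counts1 <- count_matrix(5, 3); rownames(counts1) <- cells
  ds <- make_ds(counts1, cluster = clusters, condition = rep("tumor", 5))
  lab1 <- label_reactivity(ds, call_clonotypes(contig_table(df)), "P")
  cells2 <- c(cells, "c9")
  df2 <- rbind(df, paired_contigs("c9", "ZZ"))
  counts2 <- count_matrix(6, 3); rownames(counts2) <- cells2
  ds2 <- make_ds(counts2, cluster = c(clusters, "R"), condition = rep("tumor", 6))
  lab2 <- label_reactivity(ds2, call_clonotypes(contig_table(df2)), "P")
  expect_identical(unclass(lab2)[cells], unclass(lab1)[cells])
  expect_identical(unname(unclass(lab2)["c9"]), "pTRT-irrelevant")
})
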