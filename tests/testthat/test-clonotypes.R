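test_that("paired productive chains are required and identical keys merge", {
  df <- rbind(paired_contigs("c1", "AB"), paired_contigs("c2", "AB"),
              contig_row("c3", "TRB"))
  assign <- call_clonotypes(contig_table(df))
  expect_identical(nrow(assign$cells), 2L)
  expect_identical(assign$cells$clonotype_id[1], assign$cells$clonotype_id[2])
  expect_identical(assign$unassigned$cell_id, "c3")
  expect_identical(assign$unassigned$reason, "no_productive_TRA")
  expect_identical(sum(assign$clonotypes$size), nrow(assign$cells))
})

test_that("chain selection keeps highest UMI, ties break to smallest CDR3", {
  df <- rbind(paired_contigs("c1", "A"),
              contig_row("c1", "TRB", cdr3_nt = "TTTTTTTTT", umi_count = 7L),
              contig_row("c1", "TRB", cdr3_nt = "AAAAAAAAA", umi_count = 3L))
  assign <- call_clonotypes(contig_table(df))
  expect_match(assign$clonotypes$trb_cdr3_nt, "TTTTTTTTT")
  # tie on umi -> lexicographically smallest cdr3_nt
  df2 <- rbind(paired_contigs("c1", "A"),
               contig_row("c1", "TRB", cdr3_nt = "TTTTTTTTT", umi_count = 5L),
               contig_row("c1", "TRB", cdr3_nt = "AAAAAAAAA", umi_count = 5L))
  assign2 <- call_clonotypes(contig_table(df2))
  expect_match(assign2$clonotypes$trb_cdr3_nt, "AAAAAAAAA")
  # unproductive chains are ignored entirely
  df3 <- rbind(contig_row("c1", "TRA", productive = FALSE), contig_row("c1", "TRB"))
  a3 <- call_clonotypes(contig_table(df3))
  expect_identical(a3$unassigned$reason, "no_productive_TRA")
})

test_that("clonotype calling is deterministic and idempotent", {
  df <- do.call(rbind, lapply(1:6, function(i)
    paired_contigs(paste0("c", i), sample(c("AB", "BA", "CC"), 1))))
  ct <- contig_table(df)
  expect_identical(call_clonotypes(ct), call_clonotypes(ct))
  shuffled <- contig_table(df[rev(seq_len(nrow(df))), ])
  a1 <- call_clonotypes(ct); a2 <- call_clonotypes(shuffled)
  m1 <- setNames(a1$cells$clonotype_id, a1$cells$cell_id)
  m2 <- setNames(a2$cells$clonotype_id, a2$cells$cell_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("clone sizes are computed within the requested universe", {
  df <- rbind(paired_contigs("c1", "AA"), paired_contigs("c2", "AA"),
              paired_contigs("c3", "BB"))
  assign <- call_clonotypes(contig_table(df))
  sz <- clone_sizes(assign)
  expect_identical(sort(unname(sz)), c(1L, 2L))
  sub <- clone_sizes(assign, c("c2", "c3"))
  expect_identical(sort(unname(sub)), c(1L, 1L))
  expect_identical(length(clone_sizes(assign, character(0))), 0L)
  expect_error(clone_sizes(assign, "c9"), "unassigned")
})

test_that("diversity matches the direct entropy formula", {
  cells <- paste0("c", 1:8)
  clones <- rep(c("AA", "BB", "CC"), c(4, 2, 2))
  df <- do.call(rbind, Map(paired_contigs, cells, clones))
  assign <- call_clonotypes(contig_table(df))
  d <- diversity(assign, setNames(rep("g", 8), cells))
  expect_equal(d$entropy, 1.0397, tolerance = 1e-4)
  expect_equal(d$normalized_entropy, 0.9464, tolerance = 1e-4)
  expect_equal(d$expansion_index, 1 - d$normalized_entropy)
  expect_equal(d$entropy, entropy_oracle(c(4, 2, 2)), tolerance = 1e-12)
})

test_that("uniform and single-clone groups hit the expansion extremes", {
  cells <- paste0("c", 1:4)
  df <- do.call(rbind, Map(paired_contigs, cells, c("AA", "AB", "BA", "BB")))
  d <- diversity(call_clonotypes(contig_table(df)), setNames(rep("g", 4), cells))
  expect_equal(d$normalized_entropy, 1, tolerance = 1e-12)
  expect_equal(d$expansion_index, 0, tolerance = 1e-12)
  df1 <- do.call(rbind, Map(paired_contigs, cells, rep("AA", 4)))
  d1 <- diversity(call_clonotypes(contig_table(df1)), setNames(rep("g", 4), cells))
  expect_equal(d1$normalized_entropy, 0)
  expect_equal(d1$expansion_index, 1)
  expect_error(diversity(call_clonotypes(contig_table(df1)),
                         setNames(c(rep("g", 4), "h"), c(cells, "c99"))),
               "zero assigned")
})

test_that("merging groups respects entropy concavity (direct-formula check)", {
  for (i in 1:25) {
    sizes <- with_fixed_seed(3000 + i, {
      k1 <- sample(2:6, 1); k2 <- sample(2:6, 1)
      list(a = sample(1:8, k1, replace = TRUE), b = sample(1:8, k2, replace = TRUE))
    })
    # disjoint clonotypes: merged distribution is the weighted mixture
    merged <- c(sizes$a, sizes$b)
    w1 <- sum(sizes$a) / sum(merged)
    Hm <- entropy_oracle(merged)
    expect_gte(Hm + 1e-12, w1 * entropy_oracle(sizes$a) +
                 (1 - w1) * entropy_oracle(sizes$b))
    expect_gte(Hm + 1e-12, min(entropy_oracle(sizes$a), entropy_oracle(sizes$b)))
  }
})

test_that("sharing edges enumerate all cluster pairs a clonotype spans", {
  cells <- paste0("c", 1:6)
  clones <- c("AA", "AA", "AA", "BB", "BB", "CC")
  clusters <- setNames(c("X", "X", "Y", "Y", "Z", "Z"), cells)
  df <- do.call(rbind, Map(paired_contigs, cells, clones))
  assign <- call_clonotypes(contig_table(df))
  edges <- sharing_edges(assign, clusters)
  aa_id <- assign$cells$clonotype_id[assign$cells$cell_id == "c1"]
  bb_id <- assign$cells$clonotype_id[assign$cells$cell_id == "c4"]
  expect_identical(sort(unique(edges$clonotype_id)), sort(c(aa_id, bb_id)))
  aa <- edges[edges$clonotype_id == aa_id, ]
  expect_identical(aa$cluster_i, "X"); expect_identical(aa$cluster_j, "Y")
  expect_identical(aa$n_i, 2L); expect_identical(aa$n_j, 1L)
  # spanning three clusters yields all three pairs
  df3 <- do.call(rbind, Map(paired_contigs, cells[1:3], rep("DD", 3)))
  a3 <- call_clonotypes(contig_table(df3))
  e3 <- sharing_edges(a3, setNames(c("X", "Y", "Z"), cells[1:3]))
  expect_identical(nrow(e3), 3L)
  # private clonotypes -> empty table
  e0 <- sharing_edges(assign, setNames(rep("W", 6), cells))
  expect_identical(nrow(e0), 0L)
})
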