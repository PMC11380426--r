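test_that("log1p normalization matches the hand-evaluated formula", {
  counts <- matrix(c(1, 1, 2), 1, dimnames = list("c1", c("g1", "g2", "g3")))
  ds <- normalize_log1p(expression_dataset(counts), scale_total = 4)
  expect_equal(as.numeric(ds$normalized),
               c(log(2), log(2), log(3)), tolerance = 1e-12)
})

test_that("zero-total cells normalize to zero rows with a warning", {
  counts <- matrix(c(2, 0, 3, 0), 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_warning(ds <- normalize_log1p(expression_dataset(counts)), "zero total")
  expect_identical(unname(ds$normalized["c2", ]), c(0, 0))
  expect_message(suppressWarnings(normalize_log1p(ds)), "overwriting")
})

test_that("gene set score is zero on a constant matrix", {
  counts <- matrix(5L, 6, 8,
                   dimnames = list(paste0("c", 1:6), paste0("g", 1:8)))
  ds <- normalize_log1p(expression_dataset(counts))
  sc <- score_gene_set(ds, c("g1", "g3"), seed = 1)
  expect_equal(unname(sc), rep(0, 6), tolerance = 1e-12)
})

test_that("gene set score equals the hand-computed exhaustive-pool value", {
  counts <- matrix(1L, 1, 4, dimnames = list("c1", paste0("g", 1:4)))
  norm <- matrix(c(2, 2, 0, 0), 1, dimnames = dimnames(counts))
  ds <- expression_dataset(counts, normalized = norm)
  sc <- score_gene_set(ds, "g1", n_bins = 1, n_ctrl = 3, seed = 1)
  expect_equal(unname(sc), 2 - 2 / 3, tolerance = 1e-12)
})

test_that("gene set score is deterministic given the seed and shift-invariant", {
  ds <- make_ds(count_matrix(10, 20, lambda = 2), normalize = TRUE)
  s1 <- score_gene_set(ds, c("g001", "g002"), seed = 42)
  s2 <- score_gene_set(ds, c("g001", "g002"), seed = 42)
  expect_identical(s1, s2)
  ds_shift <- ds
  ds_shift$normalized <- ds$normalized + 1.7
  s3 <- score_gene_set(ds_shift, c("g001", "g002"), n_bins = 1, seed = 42)
  s0 <- score_gene_set(ds, c("g001", "g002"), n_bins = 1, seed = 42)
  expect_equal(unname(s3), unname(s0), tolerance = 1e-12)
  expect_error(score_gene_set(ds, c("NOPE1", "NOPE2"), seed = 1), "NOPE1")
})

test_that("positive fractions count cells with any detection, per group", {
  counts <- matrix(0L, 10, 1, dimnames = list(paste0("c", 1:10), "g1"))
  counts[c(1, 3), 1] <- c(4L, 1L)
  ds <- expression_dataset(counts)
  groups <- rep(c("a", "b"), c(4, 6))
  fr <- positive_fraction(ds, "g1", groups)
  expect_equal(unname(fr[c("a", "b")]), c(0.5, 0))
  # invariant under monotone positive rescaling of counts
  ds3 <- expression_dataset(counts * 3L)
  expect_equal(positive_fraction(ds3, "g1", groups), fr)
  expect_error(positive_fraction(ds, "nope", groups), "unknown gene")
})

test_that("killing ratio is residual over input with guarded degenerate cases", {
  expect_equal(killing_ratio(5000, 20000), 0.25)
  expect_equal(killing_ratio(0, 100), 0)
  expect_equal(killing_ratio(100, 100), 1)
  expect_error(killing_ratio(10, 0), "initial_0h")
  expect_error(killing_ratio(-1, 10), "non-negative")
})

test_that("Ro/e matches the chi-square hand oracle on a 2x2 table", {
  a <- rep(c("r1", "r2"), c(40, 60))
  b <- c(rep(c("s1", "s2"), c(30, 10)), rep(c("s1", "s2"), c(10, 50)))
  roe <- roe_matrix(a, b)
  expect_equal(roe["r1", "s1"], 30 / 16, tolerance = 1e-12)
  expect_equal(roe["r2", "s1"], 10 / 24, tolerance = 1e-12)
})

test_that("Ro/e is identically one under independence", {
  # observed = outer product of margins
  a <- rep(c("x", "y"), c(20, 30))
  b <- c(rep(c("u", "v"), c(8, 12)), rep(c("u", "v"), c(12, 18)))
  roe <- roe_matrix(a, b)
  expect_equal(as.numeric(roe), rep(1, 4), tolerance = 1e-12)
})

test_that("Ro/e expected-count margins and weighted row means are exact", {
  for (i in 1:100) {
    tab <- with_fixed_seed(1000 + i, {
      nr <- sample(2:4, 1); nc <- sample(2:4, 1)
      matrix(rpois(nr * nc, 5) + 1L, nr, nc)
    })
    labs_a <- rep(rep(paste0("r", seq_len(nrow(tab))), ncol(tab)), as.vector(tab))
    labs_b <- rep(rep(paste0("c", seq_len(ncol(tab))), each = nrow(tab)), as.vector(tab))
    roe <- roe_matrix(labs_a, labs_b)
    expd <- attr(roe, "expected")
    expect_equal(sum(expd), sum(tab))
    expect_equal(unname(rowSums(expd * unclass(roe))), unname(rowSums(tab)),
                 tolerance = 1e-9)
    wmeans <- rowSums(expd * unclass(roe)) / rowSums(expd)
    expect_equal(unname(wmeans), rep(1, nrow(tab)), tolerance = 1e-9)
  }
})
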