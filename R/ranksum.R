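#' Wilcoxon rank-sum marker statistics between two cell groups
#'
#' Per-gene two-sided Mann-Whitney test on the normalized layer, with the
#' expressing fraction of each group, the log2 fold change of mean expression
#' (computed on `expm1` of the normalized values with pseudocount 1e-9) and
#' BH-adjusted p values across the tested genes.
#'
#' The exact permutation p value is computed by enumeration whenever
#' `min(n_A, n_B) <= 8` and the number of group assignments is at most 2e5;
#' otherwise the tie-corrected normal approximation is used. A gene that is
#' constant across both groups (e.g. all-zero) gets `p = 1` and is flagged
#' `untestable`.
#'
#' @param ds dataset with a normalized layer.
#' @param cells_A,cells_B disjoint cell-id vectors, each of length >= 2.
#' @param genes optional subset of genes to test (default: all).
#' @return data.frame of class `MarkerStatTable` with columns `gene`,
#'   `pct_A`, `pct_B`, `log2fc`, `U`, `p`, `p_adj`, `untestable`.
#' @export
rank_sum_markers <- function(ds, cells_A, cells_B, genes = NULL) {
  norm <- need_normalized(ds)
  ids <- cell_ids(ds)
  cells_A <- resolve_cells(cells_A, ids)
  cells_B <- resolve_cells(cells_B, ids)
  if (length(intersect(cells_A, cells_B))) stopf("cell groups overlap")
  if (length(cells_A) < 2L || length(cells_B) < 2L)
    stopf("each group needs >= 2 cells")
  genes <- genes %||% colnames(norm)
  nA <- length(cells_A); nB <- length(cells_B)
  res <- vapply(genes, function(g) {
    xa <- norm[cells_A, g]; xb <- norm[cells_B, g]
    c(ranksum_test(xa, xb),
      pct_A = mean(ds$counts[cells_A, g] > 0),
      pct_B = mean(ds$counts[cells_B, g] > 0),
      log2fc = log2((mean(expm1(xa)) + 1e-9) / (mean(expm1(xb)) + 1e-9)))
  }, c(U = 0, p = 0, untestable = 0, pct_A = 0, pct_B = 0, log2fc = 0))
  res <- as.data.frame(t(res))
  out <- data.frame(gene = genes, pct_A = res$pct_A, pct_B = res$pct_B,
                    log2fc = res$log2fc, U = res$U, p = res$p,
                    p_adj = stats::p.adjust(res$p, "BH"),
                    untestable = res$untestable > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("MarkerStatTable", "data.frame")
  out
}

resolve_cells <- function(cells, ids) {
  if (is.numeric(cells)) return(ids[cells])
  cells <- as.character(cells)
  miss <- setdiff(cells, ids)
  if (length(miss)) stopf("unknown cell id(s): %s",
                          paste(utils::head(miss, 5L), collapse = ", "))
  cells
}

# two-sided Mann-Whitney for one gene; returns c(U, p, untestable)
ranksum_test <- function(xa, xb, exact_limit = 2e5) {
  nA <- length(xa); nB <- length(xb); N <- nA + nB
  r <- rank(c(xa, xb))
  wA <- sum(r[seq_len(nA)])
  U <- wA - nA * (nA + 1) / 2
  if (stats::var(c(xa, xb)) == 0) return(c(U = U, p = 1, untestable = 1))
  m <- min(nA, nB)
  if (m <= 8L && choose(N, m) <= exact_limit) {
    # exact permutation distribution of the smaller group's rank sum
    Em <- m * (N + 1) / 2
    wobs <- if (nA <= nB) wA else sum(r[(nA + 1):N])
    idx <- utils::combn(N, m)
    sums <- colSums(matrix(r[idx], nrow = m))
    p <- mean(abs(sums - Em) >= abs(wobs - Em) - 1e-9)
  } else {
    # normal approximation with tie correction
    ties <- table(r)
    muU <- nA * nB / 2
    sigU <- sqrt(nA * nB / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    if (sigU == 0) return(c(U = U, p = 1, untestable = 1))
    z <- (U - muU) / sigU
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  c(U = U, p = p, untestable = 0)
}
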