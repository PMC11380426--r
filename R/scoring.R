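#' Library-size normalization and log transformation
#'
#' Sets the normalized layer to `ln(1 + scale_total * count / cell_total)`,
#' the standard per-cell depth normalization followed by log1p. Cells with
#' zero total counts get an all-zero normalized row and a warning.
#'
#' @param ds an [expression_dataset()].
#' @param scale_total target per-cell total (default 1e4).
#' @return the dataset with `$normalized` set.
#' @export
normalize_log1p <- function(ds, scale_total = 1e4) {
  stopifnot(inherits(ds, "ExpressionDataset"), scale_total > 0)
  if (!is.null(ds$normalized))
    message("overwriting existing normalized layer")
  totals <- rowSums(ds$counts)
  zero <- totals == 0
  if (any(zero)) {
    warnf("%d cell(s) with zero total counts set to all-zero normalized rows", sum(zero))
    totals[zero] <- 1
  }
  ds$normalized <- log1p(scale_total * ds$counts / totals)
  ds
}

need_normalized <- function(ds) {
  if (is.null(ds$normalized))
    stopf("normalized layer missing; run normalize_log1p() first")
  ds$normalized
}

#' Control-pool gene set score
#'
#' The community-standard binned control-pool score: genes are binned by
#' dataset-mean normalized expression into `n_bins` bins; for every set gene,
#' `n_ctrl` control genes are sampled (seeded, without replacement, set genes
#' excluded) from the same bin; the per-cell score is the mean normalized
#' expression over the set minus the mean over the pooled control genes.
#'
#' @param ds dataset with normalized layer.
#' @param genes character vector of set gene symbols; at least one must be
#'   present in the dataset.
#' @param n_bins number of average-expression bins (default 25, capped at
#'   the number of genes).
#' @param n_ctrl control genes drawn per set gene (default 50; capped at bin
#'   occupancy).
#' @param seed RNG seed for the control draw.
#' @return named numeric vector, one score per cell.
#' @export
score_gene_set <- function(ds, genes, n_bins = 25, n_ctrl = 50, seed = 0) {
  norm <- need_normalized(ds)
  present <- intersect(genes, colnames(norm))
  if (!length(present))
    stopf("no set gene found in dataset; missing: %s", paste(genes, collapse = ", "))
  gmeans <- colMeans(norm)
  # keep bins populated enough to supply non-set control genes
  n_bins <- max(1L, min(as.integer(n_bins), ncol(norm) %/% 4L))
  bins <- if (n_bins == 1L) rep(1L, ncol(norm))
          else cut(rank(gmeans, ties.method = "first"), breaks = n_bins,
                   labels = FALSE)
  names(bins) <- colnames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      pool <- setdiff(pool, genes)
      if (!length(pool)) return(character(0))
      sample(pool, min(n_ctrl, length(pool)))
    }), use.names = FALSE)
  })
  set_mean <- rowMeans(norm[, present, drop = FALSE])
  if (!length(ctrl))
    stopf("control pool is empty; reduce n_bins or the set size")
  ctrl_mean <- rowMeans(norm[, ctrl, drop = FALSE])
  set_mean - ctrl_mean
}

#' Fraction of cells expressing a gene, by group
#'
#' A cell "expresses" a gene when its raw count is > 0 (dot-plot semantics);
#' the result is therefore invariant to any monotone positive rescaling of
#' counts.
#'
#' @param ds dataset.
#' @param gene gene symbol.
#' @param groups per-cell categorical labels (length = number of cells, or
#'   named by cell id).
#' @return named numeric vector of fractions in `[0, 1]`, one per group level.
#' @export
positive_fraction <- function(ds, gene, groups) {
  if (!gene %in% gene_ids(ds)) stopf("unknown gene: %s", gene)
  groups <- align_labels(groups, cell_ids(ds))
  pos <- ds$counts[, gene] > 0
  out <- tapply(pos, groups, mean)
  setNames(as.numeric(out), names(out))
}

align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) stopf("labels missing for %d cell(s)", length(miss))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stopf("labels length %d does not match %d cells", length(labels), length(ids))
  }
  as.character(labels)
}

#' Cell-killing ratio
#'
#' Residual blast count after coculture divided by the input blast count:
#' 0 = complete killing, 1 = no killing.
#'
#' @param residual_24h absolute residual blast count at 24 h.
#' @param initial_0h absolute blast count at 0 h (must be > 0).
#' @return `residual_24h / initial_0h`.
#' @export
killing_ratio <- function(residual_24h, initial_0h) {
  if (any(initial_0h <= 0)) stopf("initial_0h must be > 0")
  if (any(residual_24h < 0)) stopf("counts must be non-negative")
  residual_24h / initial_0h
}

#' Ro/e enrichment matrix
#'
#' Ratio of observed to expected cell counts under independence of two
#' per-cell labelings: `Roe(i,j) = O_ij / E_ij` with
#' `E_ij = row_i * col_j / N` (the chi-square expected counts). Values > 1
#' indicate enrichment of level i in level j.
#'
#' @param labels_a,labels_b per-cell categorical labels over the same cells.
#' @return matrix of class `EnrichmentMatrix` with the expected counts in
#'   `attr(x, "expected")`.
#' @export
roe_matrix <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b))
    stopf("labelings cover different numbers of cells")
  obs <- table(labels_a, labels_b)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0))
    stopf("empty level in labeling")
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  out <- unclass(obs) / expd
  structure(out, expected = expd, class = c("EnrichmentMatrix", "matrix"))
}
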