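#' Per-cluster pTRT indices
#'
#' Computes the four indices that characterize potentially tumor-reactive
#' T-cell (pTRT) clusters:
#' \describe{
#'   \item{tumor_enrichment_index}{Ro/e of the cluster in the tumor condition
#'     (cluster x condition table, tumor column).}
#'   \item{clonal_expansion_index}{`1 - normalized Shannon entropy` of the
#'     cluster's tumor-condition assigned cells.}
#'   \item{proliferation_index}{fraction of cluster cells with any
#'     proliferation-marker count > 0.}
#'   \item{z_<set>}{per-cluster mean TCR-signaling control-pool score,
#'     z-scored across clusters, one column per signaling set.}
#' }
#' Clusters with fewer than `min_tumor_cells` tumor-condition cells are
#' flagged `insufficient` and excluded from calling (small-sample entropy is
#' unstable).
#'
#' @param ds dataset with `cluster` and `condition` metadata and a
#'   normalized layer.
#' @param assign a [call_clonotypes()] result.
#' @param signaling_sets a [gene_set_collection()]
#'   (default [default_tcr_signaling_sets()]).
#' @param proliferation_genes marker set for cycling cells
#'   (default MKI67, TOP2A, PCNA; positivity = any member detected).
#' @param tumor_level the condition level regarded as tumor (default "tumor").
#' @param min_tumor_cells minimum tumor cells for a callable cluster
#'   (default 20).
#' @param n_bins,n_ctrl,seed passed to [score_gene_set()].
#' @return data.frame of class `ClusterIndexTable`.
#' @export
compute_cluster_indices <- function(ds, assign,
                                    signaling_sets = default_tcr_signaling_sets(),
                                    proliferation_genes = c("MKI67", "TOP2A", "PCNA"),
                                    tumor_level = "tumor",
                                    min_tumor_cells = 20,
                                    n_bins = 25, n_ctrl = 50, seed = 0) {
  cl <- ds$cell_meta$cluster
  cond <- ds$cell_meta$condition
  if (anyNA(cl) || anyNA(cond))
    stopf("cluster/condition metadata must be complete")
  if (!tumor_level %in% cond) stopf("no cell with condition '%s'", tumor_level)
  ids <- cell_ids(ds)
  clusters <- sort(unique(cl))

  roe <- roe_matrix(cl, cond)
  enrich <- roe[clusters, tumor_level]

  # clonal expansion on tumor-condition assigned cells per cluster
  tumor_ids <- ids[cond == tumor_level]
  named_cl <- setNames(cl, ids)
  assigned_tumor <- intersect(assign$cells$cell_id, tumor_ids)
  n_tumor <- vapply(clusters, function(g) sum(cl == g & cond == tumor_level), 0)
  expansion <- setNames(rep(NA_real_, length(clusters)), clusters)
  if (length(assigned_tumor)) {
    sub_labels <- named_cl[assigned_tumor]
    for (g in unique(sub_labels)) {
      cells_g <- assigned_tumor[sub_labels == g]
      sizes <- clone_sizes(assign, cells_g)
      p <- sizes / sum(sizes)
      H <- -sum(p * log(p))
      expansion[g] <- if (length(sizes) == 1L) 1 else 1 - H / log(length(sizes))
    }
  }

  prolif_present <- intersect(proliferation_genes, gene_ids(ds))
  if (!length(prolif_present))
    stopf("no proliferation marker found in dataset: %s",
          paste(proliferation_genes, collapse = ", "))
  pos_any <- rowSums(ds$counts[, prolif_present, drop = FALSE] > 0) > 0
  prolif <- vapply(clusters, function(g) mean(pos_any[cl == g]), 0)

  zmat <- vapply(seq_along(signaling_sets), function(i) {
    sc <- score_gene_set(ds, signaling_sets[[i]], n_bins = n_bins,
                         n_ctrl = n_ctrl, seed = seed + i)
    m <- vapply(clusters, function(g) mean(sc[cl == g]), 0)
    s <- stats::sd(m)
    if (is.na(s) || s == 0) rep(0, length(m)) else (m - mean(m)) / s
  }, numeric(length(clusters)))
  colnames(zmat) <- paste0("z_", names(signaling_sets))

  insufficient <- n_tumor < min_tumor_cells
  out <- data.frame(cluster = clusters,
                    n_cells = as.integer(vapply(clusters, function(g) sum(cl == g), 0)),
                    n_tumor_cells = as.integer(n_tumor),
                    tumor_enrichment_index = as.numeric(enrich),
                    clonal_expansion_index = as.numeric(expansion),
                    proliferation_index = as.numeric(prolif),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, zmat)
  out$insufficient <- insufficient
  class(out) <- c("ClusterIndexTable", "data.frame")
  out
}

#' Call pTRT clusters from the index table
#'
#' A cluster is flagged pTRT when all four criteria hold:
#' enrichment >= `tau_enrichment`, expansion >= `tau_expansion`,
#' proliferation >= `tau_proliferation`, and the median of its signaling
#' z-scores > `tau_signaling`. Clusters flagged `insufficient` are never
#' called. A warning (not an error) is raised when no cluster or every
#' cluster is flagged.
#'
#' @param idx a [compute_cluster_indices()] table.
#' @param tau_enrichment,tau_expansion,tau_proliferation,tau_signaling
#'   thresholds (defaults 1.2, 0.2, 0.05, 0).
#' @return the table with logical column `is_ptrt` and the thresholds in
#'   `attr(x, "thresholds")`.
#' @export
call_ptrt_clusters <- function(idx, tau_enrichment = 1.2, tau_expansion = 0.2,
                               tau_proliferation = 0.05, tau_signaling = 0) {
  stopifnot(inherits(idx, "ClusterIndexTable"))
  zc <- grep("^z_", names(idx), value = TRUE)
  medz <- apply(as.matrix(idx[, zc, drop = FALSE]), 1L, stats::median)
  ok <- !idx$insufficient &
    !is.na(idx$clonal_expansion_index) &
    idx$tumor_enrichment_index >= tau_enrichment &
    idx$clonal_expansion_index >= tau_expansion &
    idx$proliferation_index >= tau_proliferation &
    medz > tau_signaling
  idx$median_signaling_z <- medz
  idx$is_ptrt <- ok
  if (!any(ok)) warnf("no cluster passed the pTRT criteria")
  if (all(ok)) warnf("every cluster passed the pTRT criteria")
  attr(idx, "thresholds") <- c(tau_enrichment = tau_enrichment,
                               tau_expansion = tau_expansion,
                               tau_proliferation = tau_proliferation,
                               tau_signaling = tau_signaling)
  idx
}

#' Three-way reactivity labels
#'
#' Cells in pTRT clusters are labeled `pTRT`; cells outside whose clonotype
#' appears on at least one pTRT cell are `pTRT-relevant`; all others —
#' including cells with no assigned clonotype — are `pTRT-irrelevant`.
#' Tumor-reactive = pTRT plus pTRT-relevant.
#'
#' @param ds dataset with cluster metadata.
#' @param assign a [call_clonotypes()] result.
#' @param ptrt_clusters character vector of pTRT cluster names (or a
#'   [call_ptrt_clusters()] table, from which flagged clusters are taken).
#' @return named character vector of labels over all cells, class
#'   `ReactivityLabels`.
#' @export
label_reactivity <- function(ds, assign, ptrt_clusters) {
  if (inherits(ptrt_clusters, "ClusterIndexTable"))
    ptrt_clusters <- ptrt_clusters$cluster[ptrt_clusters$is_ptrt]
  ids <- cell_ids(ds)
  cl <- setNames(ds$cell_meta$cluster, ids)
  labels <- setNames(rep("pTRT-irrelevant", length(ids)), ids)
  in_ptrt <- cl %in% ptrt_clusters
  labels[in_ptrt] <- "pTRT"
  ct <- setNames(assign$cells$clonotype_id, assign$cells$cell_id)
  ptrt_cells_with_ct <- intersect(names(ct), ids[in_ptrt])
  shared <- unique(ct[ptrt_cells_with_ct])
  outside <- intersect(names(ct), ids[!in_ptrt])
  rel <- outside[ct[outside] %in% shared]
  labels[rel] <- "pTRT-relevant"
  structure(labels, class = "ReactivityLabels")
}

#' Fraction of pTRT-relevant cells per cluster
#'
#' pTRT clusters report 0 by construction (their cells are labeled pTRT).
#'
#' @param labels a [label_reactivity()] vector.
#' @param cluster_labels named per-cell cluster labels.
#' @return named numeric vector of fractions per cluster.
#' @export
relevant_composition <- function(labels, cluster_labels) {
  if (is.null(names(cluster_labels)))
    stopf("cluster_labels must be named by cell id")
  cl <- as.character(cluster_labels[names(labels)])
  out <- tapply(unclass(labels) == "pTRT-relevant", cl, mean)
  setNames(as.numeric(out), names(out))
}
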