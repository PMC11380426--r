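#' Fit the tumor-reactivity model to a paired scRNA + scTCR cohort
#'
#' The package's central entry point. Given a clustered, condition-annotated
#' expression dataset and its TCR contigs, `ptrt()`:
#' \enumerate{
#'   \item normalizes the counts (unless a normalized layer is present),
#'   \item calls clonotypes from paired productive chains,
#'   \item computes the four per-cluster indices (tumor enrichment Ro/e,
#'     clonal expansion, proliferation, TCR-signaling activation),
#'   \item calls pTRT clusters by the conjunction-of-thresholds rule, and
#'   \item traces pTRT-relevant cells through shared clonotypes, yielding
#'     the three-way per-cell reactivity label.
#' }
#'
#' @param ds an [expression_dataset()] with `cluster` and `condition`
#'   metadata.
#' @param contigs a [contig_table()] (or a precomputed
#'   [call_clonotypes()] object).
#' @param signaling_sets,proliferation_genes,tumor_level,min_tumor_cells,n_bins,n_ctrl
#'   passed to [compute_cluster_indices()].
#' @param tau_enrichment,tau_expansion,tau_proliferation,tau_signaling
#'   calling thresholds, see [call_ptrt_clusters()].
#' @param scale_total normalization target, see [normalize_log1p()].
#' @param seed RNG seed for the control-pool scores.
#' @return object of class `ptrt_fit` with components `dataset`,
#'   `clonotypes`, `indices`, `ptrt_clusters`, `labels`, `thresholds`.
#'   Methods: `print`, `summary`, `coef` (the cluster index matrix),
#'   `fitted` (the per-cell labels).
#' @export
ptrt <- function(ds, contigs,
                 signaling_sets = default_tcr_signaling_sets(),
                 proliferation_genes = c("MKI67", "TOP2A", "PCNA"),
                 tumor_level = "tumor", min_tumor_cells = 20,
                 n_bins = 25, n_ctrl = 50,
                 tau_enrichment = 1.2, tau_expansion = 0.2,
                 tau_proliferation = 0.05, tau_signaling = 0,
                 scale_total = 1e4, seed = 0) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(ds$normalized)) ds <- normalize_log1p(ds, scale_total)
  assign <- if (inherits(contigs, "ClonotypeAssignment")) contigs
            else call_clonotypes(contigs)
  idx <- compute_cluster_indices(ds, assign, signaling_sets = signaling_sets,
                                 proliferation_genes = proliferation_genes,
                                 tumor_level = tumor_level,
                                 min_tumor_cells = min_tumor_cells,
                                 n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  idx <- call_ptrt_clusters(idx, tau_enrichment = tau_enrichment,
                            tau_expansion = tau_expansion,
                            tau_proliferation = tau_proliferation,
                            tau_signaling = tau_signaling)
  ptrt_clusters <- idx$cluster[idx$is_ptrt]
  labels <- label_reactivity(ds, assign, ptrt_clusters)
  structure(list(dataset = ds, clonotypes = assign, indices = idx,
                 ptrt_clusters = ptrt_clusters, labels = labels,
                 thresholds = attr(idx, "thresholds"), seed = seed),
            class = "ptrt_fit")
}

#' @export
print.ptrt_fit <- function(x, ...) {
  tal <- table(unclass(x$labels))
  cat(sprintf("ptrt_fit: %d cells, %d clusters, %d pTRT cluster(s): %s\n",
              nrow(x$dataset$counts), nrow(x$indices),
              length(x$ptrt_clusters),
              if (length(x$ptrt_clusters)) paste(x$ptrt_clusters, collapse = ", ")
              else "(none)"))
  cat("  labels:", paste(sprintf("%s=%d", names(tal), tal), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.ptrt_fit <- function(object, ...) {
  out <- list(indices = object$indices,
              ptrt_clusters = object$ptrt_clusters,
              label_tally = table(unclass(object$labels)),
              relevant_composition = relevant_composition(
                object$labels,
                setNames(object$dataset$cell_meta$cluster,
                         rownames(object$dataset$cell_meta))),
              thresholds = object$thresholds)
  class(out) <- "summary.ptrt_fit"
  out
}

#' @export
print.summary.ptrt_fit <- function(x, ...) {
  cat("pTRT cluster indices:\n")
  cols <- c("cluster", "n_cells", "tumor_enrichment_index",
            "clonal_expansion_index", "proliferation_index",
            "median_signaling_z", "is_ptrt")
  print(format(x$indices[, cols], digits = 3), row.names = FALSE)
  cat("\nThresholds:", paste(sprintf("%s=%g", names(x$thresholds), x$thresholds),
                             collapse = "  "), "\n")
  cat("Labels:", paste(sprintf("%s=%d", names(x$label_tally), x$label_tally),
                       collapse = "  "), "\n")
  cat("\npTRT-relevant composition (top clusters):\n")
  comp <- sort(x$relevant_composition, decreasing = TRUE)
  print(round(utils::head(comp, 5L), 4))
  invisible(x)
}

#' @export
coef.ptrt_fit <- function(object, ...) {
  m <- as.matrix(object$indices[, c("tumor_enrichment_index",
                                    "clonal_expansion_index",
                                    "proliferation_index",
                                    "median_signaling_z")])
  rownames(m) <- object$indices$cluster
  m
}

#' @export
fitted.ptrt_fit <- function(object, ...) object$labels
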