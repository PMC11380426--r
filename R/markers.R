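#' Rank genes by specificity for tumor-reactive cells
#'
#' Implements the bystander-filter / delta / precision ranking:
#' \enumerate{
#'   \item bystander cells = `pTRT-irrelevant`; reactive = pTRT and
#'     pTRT-relevant cells;
#'   \item candidate genes must have mean normalized expression in bystander
#'     cells below `bystander_mean_cutoff` (default 0.5, on the
#'     log-normalized scale);
#'   \item candidates are ranked by the delta value — by default the
#'     difference in expressing-cell fractions (reactive minus bystander) —
#'     and truncated to the `top_k` (default 100);
#'   \item for those genes the reactive-cell precision is computed: the
#'     fraction of all expressing cells that are tumor-reactive; the final
#'     rank orders candidates by precision (ties: larger delta, then symbol).
#' }
#'
#' @param ds dataset with a normalized layer.
#' @param labels a [label_reactivity()] vector (or any per-cell vector with
#'   levels pTRT / pTRT-relevant / pTRT-irrelevant).
#' @param bystander_mean_cutoff bystander mean-expression filter (default 0.5).
#' @param top_k number of delta-ranked candidates retained (default 100).
#' @param delta `"fraction"` (expressing-fraction difference, default) or
#'   `"mean"` (normalized-mean difference).
#' @return data.frame of class `MarkerRanking`, one row per gene, with
#'   `bystander_mean`, `reactive_mean`, `delta`, `candidate`, `precision`,
#'   `rank` (NA outside the candidate set).
#' @export
rank_marker_candidates <- function(ds, labels, bystander_mean_cutoff = 0.5,
                                   top_k = 100, delta = c("fraction", "mean")) {
  delta <- match.arg(delta)
  norm <- need_normalized(ds)
  if (top_k < 1) stopf("top_k must be >= 1")
  lab <- align_labels(unclass(labels), cell_ids(ds))
  reactive <- lab != "pTRT-irrelevant"
  if (!any(reactive) || all(reactive))
    stopf("both reactive and bystander groups must be non-empty")
  bys_mean <- colMeans(norm[!reactive, , drop = FALSE])
  react_mean <- colMeans(norm[reactive, , drop = FALSE])
  expr <- ds$counts > 0
  frac_r <- colMeans(expr[reactive, , drop = FALSE])
  frac_b <- colMeans(expr[!reactive, , drop = FALSE])
  dval <- if (delta == "fraction") frac_r - frac_b else react_mean - bys_mean
  genes <- gene_ids(ds)
  out <- data.frame(gene = genes, bystander_mean = bys_mean,
                    reactive_mean = react_mean, delta = dval,
                    frac_reactive = frac_r, frac_bystander = frac_b,
                    candidate = FALSE, precision = NA_real_, rank = NA_integer_,
                    stringsAsFactors = FALSE, row.names = NULL)
  pass <- which(bys_mean < bystander_mean_cutoff)
  ord <- pass[order(-dval[pass], genes[pass])]
  cand <- ord[seq_len(min(top_k, length(ord)))]
  out$candidate[cand] <- TRUE
  n_expr <- colSums(expr[, cand, drop = FALSE])
  n_expr_r <- colSums(expr[reactive, cand, drop = FALSE])
  out$precision[cand] <- ifelse(n_expr > 0, n_expr_r / n_expr, NA_real_)
  ranked <- cand[order(-out$precision[cand], -out$delta[cand], out$gene[cand],
                       na.last = TRUE)]
  out$rank[ranked] <- seq_along(ranked)
  class(out) <- c("MarkerRanking", "data.frame")
  out
}

#' Flag cells carrying virus-specific clonotypes
#'
#' Exact-match screening of TRB CDR3 amino-acid sequences against a
#' user-supplied reference (e.g. a VDJdb export): a cell is flagged when its
#' clonotype's CDR3beta equals a reference entry and, where the reference row
#' specifies a V gene, the V gene matches too. Unassigned cells are never
#' flagged. This is an exact-match substitution for model-based specificity
#' prediction, not a reproduction of one.
#'
#' @param assign a [call_clonotypes()] result.
#' @param reference data.frame with columns `cdr3_aa_beta`, optional
#'   `v_gene` (NA or "" = any), optional `species`.
#' @return data.frame `cell_id`, `viral_tcr` over all cells known to the
#'   assignment (assigned and unassigned).
#' @export
flag_viral_clonotypes <- function(assign, reference) {
  stopifnot(inherits(assign, "ClonotypeAssignment"))
  if (!NROW(reference)) stopf("viral reference is empty")
  if (!"cdr3_aa_beta" %in% names(reference))
    stopf("viral reference must have a 'cdr3_aa_beta' column")
  ref_cdr3 <- toupper(as.character(reference$cdr3_aa_beta))
  if (anyNA(ref_cdr3) || any(!nzchar(ref_cdr3)))
    stopf("malformed viral reference row(s): empty cdr3_aa_beta")
  ref_v <- as.character(reference$v_gene %||% rep(NA_character_, length(ref_cdr3)))
  ref_v[!is.na(ref_v) & ref_v == ""] <- NA_character_
  ct <- assign$clonotypes
  hit <- vapply(seq_len(nrow(ct)), function(i) {
    j <- which(ref_cdr3 == ct$trb_cdr3_aa[i])
    any(is.na(ref_v[j]) | ref_v[j] == ct$trb_v[i])
  }, logical(1L))
  viral_ct <- ct$clonotype_id[hit]
  cells <- rbind(
    data.frame(cell_id = assign$cells$cell_id,
               viral_tcr = assign$cells$clonotype_id %in% viral_ct,
               stringsAsFactors = FALSE),
    data.frame(cell_id = assign$unassigned$cell_id, viral_tcr = FALSE,
               stringsAsFactors = FALSE))
  rownames(cells) <- NULL
  class(cells) <- c("ViralAnnotation", "data.frame")
  attr(cells, "viral_clonotypes") <- viral_ct
  cells
}

#' Marker expressing fraction among viral-TCR cells
#'
#' @param ds dataset.
#' @param viral a [flag_viral_clonotypes()] table.
#' @param gene gene of interest (e.g. "ADGRG1").
#' @return fraction of flagged cells with count > 0.
#' @export
marker_expression_in_viral <- function(ds, viral, gene) {
  flagged <- viral$cell_id[viral$viral_tcr]
  flagged <- intersect(flagged, cell_ids(ds))
  if (!length(flagged)) stopf("no viral-flagged cell present in the dataset")
  if (!gene %in% gene_ids(ds)) stopf("unknown gene: %s", gene)
  mean(ds$counts[flagged, gene] > 0)
}
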