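#' Call clonotypes from paired productive chains
#'
#' A cell is assigned a clonotype when it carries at least one productive TRA
#' and one productive TRB contig; otherwise it is recorded as unassigned with
#' reason `no_productive_TRA` / `no_productive_TRB`. When several productive
#' chains of one locus exist, the highest-UMI chain is kept (ties broken by
#' lexicographically smallest CDR3 nucleotide sequence). The clonotype key is
#' the tuple (TRA V, J, CDR3nt; TRB V, J, CDR3nt) — or the amino-acid CDR3s
#' with `use_aa = TRUE` for cross-donor comparisons. The call is
#' deterministic and idempotent.
#'
#' @param contigs a [contig_table()].
#' @param use_aa use amino-acid CDR3s in the clonotype key (default FALSE).
#' @return object of class `ClonotypeAssignment`: list with `cells`
#'   (cell_id, clonotype_id), `clonotypes` (key fields plus clone `size`),
#'   and `unassigned` (cell_id, reason).
#' @export
call_clonotypes <- function(contigs, use_aa = FALSE) {
  stopifnot(inherits(contigs, "ContigTable"))
  prod <- contigs[contigs$productive, , drop = FALSE]
  # best productive chain per (cell, locus): max umi, ties -> smallest cdr3_nt
  ord <- order(prod$cell_id, prod$chain, -prod$umi_count, prod$cdr3_nt,
               method = "radix")
  prod <- prod[ord, , drop = FALSE]
  best <- prod[!duplicated(prod[, c("cell_id", "chain")]), , drop = FALSE]
  tra <- best[best$chain == "TRA", , drop = FALSE]
  trb <- best[best$chain == "TRB", , drop = FALSE]
  all_cells <- unique(contigs$cell_id)
  has_tra <- all_cells %in% tra$cell_id
  has_trb <- all_cells %in% trb$cell_id
  assigned <- all_cells[has_tra & has_trb]
  unassigned <- data.frame(
    cell_id = all_cells[!(has_tra & has_trb)],
    reason = ifelse(!has_tra[!(has_tra & has_trb)],
                    "no_productive_TRA", "no_productive_TRB"),
    stringsAsFactors = FALSE)
  ia <- match(assigned, tra$cell_id)
  ib <- match(assigned, trb$cell_id)
  cdr3a <- if (use_aa) tra$cdr3_aa[ia] else tra$cdr3_nt[ia]
  cdr3b <- if (use_aa) trb$cdr3_aa[ib] else trb$cdr3_nt[ib]
  key <- paste(tra$v_gene[ia], tra$j_gene[ia], cdr3a,
               trb$v_gene[ib], trb$j_gene[ib], cdr3b, sep = "|")
  fac <- factor(key)
  ct_id <- sprintf("ct%05d", as.integer(fac))
  first <- !duplicated(key)
  clonotypes <- data.frame(
    clonotype_id = ct_id[first],
    tra_v = tra$v_gene[ia][first], tra_j = tra$j_gene[ia][first],
    tra_cdr3_nt = tra$cdr3_nt[ia][first], tra_cdr3_aa = tra$cdr3_aa[ia][first],
    trb_v = trb$v_gene[ib][first], trb_j = trb$j_gene[ib][first],
    trb_cdr3_nt = trb$cdr3_nt[ib][first], trb_cdr3_aa = trb$cdr3_aa[ib][first],
    stringsAsFactors = FALSE)
  clonotypes <- clonotypes[order(clonotypes$clonotype_id), , drop = FALSE]
  sz <- table(ct_id)
  clonotypes$size <- as.integer(sz[clonotypes$clonotype_id])
  rownames(clonotypes) <- NULL
  structure(list(
    cells = data.frame(cell_id = assigned, clonotype_id = ct_id,
                       stringsAsFactors = FALSE),
    clonotypes = clonotypes,
    unassigned = unassigned,
    use_aa = use_aa), class = "ClonotypeAssignment")
}

#' @export
print.ClonotypeAssignment <- function(x, ...) {
  cat(sprintf("ClonotypeAssignment: %d cells in %d clonotypes (%d unassigned)\n",
              nrow(x$cells), nrow(x$clonotypes), nrow(x$unassigned)))
  invisible(x)
}

#' Clone sizes within an analysis universe
#'
#' Clone size is always computed within the chosen universe of cells (e.g.
#' the tumor compartment), not globally.
#'
#' @param assign a [call_clonotypes()] result.
#' @param cells optional cell-id subset (must be assigned cells).
#' @return named integer vector clonotype_id -> cell count.
#' @export
clone_sizes <- function(assign, cells = NULL) {
  stopifnot(inherits(assign, "ClonotypeAssignment"))
  tab <- assign$cells
  if (!is.null(cells)) {
    bad <- setdiff(cells, tab$cell_id)
    if (length(bad)) stopf("subset contains unassigned/unknown cell(s): %s",
                           paste(utils::head(bad, 5L), collapse = ", "))
    tab <- tab[tab$cell_id %in% cells, , drop = FALSE]
  }
  if (!nrow(tab)) return(integer(0))
  out <- table(tab$clonotype_id)
  setNames(as.integer(out), names(out))
}

#' Shannon-entropy diversity and expansion index by group
#'
#' For clone-size proportions `p_i` within each group:
#' `H = -sum(p_i log p_i)` (nats), normalized entropy `H / ln(k)` for `k`
#' clonotypes, and expansion index `1 - H/ln(k)`. A single-clone group has
#' normalized entropy 0 and expansion 1 by the limit convention. Clone
#' proportions are counted over cells.
#'
#' @param assign a [call_clonotypes()] result.
#' @param group_labels named per-cell categorical vector (names = cell ids)
#'   covering at least the assigned cells; every group level must contain at
#'   least one assigned cell.
#' @return data.frame of class `DiversityStats` with columns `group`,
#'   `n_cells`, `k`, `entropy`, `normalized_entropy`, `expansion_index`.
#' @export
diversity <- function(assign, group_labels) {
  stopifnot(inherits(assign, "ClonotypeAssignment"))
  if (is.null(names(group_labels)))
    stopf("group_labels must be named by cell id")
  tab <- assign$cells
  miss <- setdiff(tab$cell_id, names(group_labels))
  if (length(miss)) stopf("group label missing for %d assigned cell(s)", length(miss))
  grp <- as.character(group_labels[tab$cell_id])
  levels <- unique(as.character(group_labels))
  rows <- lapply(sort(unique(grp)), function(g) {
    sizes <- table(tab$clonotype_id[grp == g])
    p <- as.numeric(sizes) / sum(sizes)
    H <- -sum(p * log(p))
    k <- length(p)
    Hn <- if (k == 1L) 0 else H / log(k)
    data.frame(group = g, n_cells = sum(sizes), k = k, entropy = H,
               normalized_entropy = Hn, expansion_index = 1 - Hn,
               stringsAsFactors = FALSE)
  })
  empty <- setdiff(levels, unique(grp))
  if (length(empty))
    stopf("group(s) with zero assigned cells: %s", paste(empty, collapse = ", "))
  out <- do.call(rbind, rows)
  class(out) <- c("DiversityStats", "data.frame")
  out
}

#' Clonotypes shared across clusters
#'
#' One row per clonotype and unordered cluster pair it spans, with the cell
#' counts in each cluster — the tracing substrate for pTRT-relevant cells.
#'
#' @param assign a [call_clonotypes()] result.
#' @param cluster_labels named per-cell cluster labels covering assigned cells.
#' @return data.frame `clonotype_id`, `cluster_i`, `cluster_j`, `n_i`, `n_j`.
#' @export
sharing_edges <- function(assign, cluster_labels) {
  stopifnot(inherits(assign, "ClonotypeAssignment"))
  if (is.null(names(cluster_labels)))
    stopf("cluster_labels must be named by cell id")
  tab <- assign$cells
  cl <- as.character(cluster_labels[tab$cell_id])
  if (anyNA(cl)) stopf("cluster label missing for assigned cell(s)")
  counts <- table(tab$clonotype_id, cl)
  rows <- list()
  for (ct in rownames(counts)) {
    present <- colnames(counts)[counts[ct, ] > 0]
    if (length(present) < 2L) next
    pairs <- utils::combn(sort(present), 2L)
    rows[[ct]] <- data.frame(
      clonotype_id = ct, cluster_i = pairs[1L, ], cluster_j = pairs[2L, ],
      n_i = as.integer(counts[ct, pairs[1L, ]]),
      n_j = as.integer(counts[ct, pairs[2L, ]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(clonotype_id = character(0), cluster_i = character(0),
                      cluster_j = character(0), n_i = integer(0),
                      n_j = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
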