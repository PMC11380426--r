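#' Build a signature matrix from labeled single cells
#'
#' For each cell state, genes are tested by rank-sum against all other
#' states; genes with BH-adjusted p < `alpha` and enrichment in the state
#' (AUC > 0.5) are ranked by AUC and the top `n_top` retained. The signature
#' gene list is the union across states; matrix entries are the per-state
#' mean of `expm1(normalized)` over signature genes.
#'
#' @param ds dataset with a normalized layer.
#' @param state_labels per-cell state labels (named by cell id or aligned);
#'   every state needs >= 10 cells.
#' @param n_top genes retained per state (default 50).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return object of class `SignatureMatrix`: list with `profiles`
#'   (genes x states), `states`, `genes`, and the per-state marker tables in
#'   `markers`.
#' @export
build_signature <- function(ds, state_labels, n_top = 50, alpha = 0.05) {
  norm <- need_normalized(ds)
  lab <- align_labels(state_labels, cell_ids(ds))
  states <- sort(unique(lab))
  if (length(states) < 2L) stopf("need >= 2 states")
  n_per <- table(lab)
  small <- names(n_per)[n_per < 10L]
  if (length(small)) stopf("state(s) below 10 cells: %s", paste(small, collapse = ", "))
  ids <- cell_ids(ds)
  picks <- list(); markers <- list()
  for (st in states) {
    stat <- rank_sum_markers(ds, ids[lab == st], ids[lab != st])
    nA <- sum(lab == st); nB <- sum(lab != st)
    stat$auc <- stat$U / (nA * nB)
    sig <- stat[!stat$untestable & stat$p_adj < alpha & stat$auc > 0.5, , drop = FALSE]
    if (!nrow(sig)) stopf("no significant signature gene for state: %s", st)
    sig <- sig[order(-sig$auc, -sig$log2fc, sig$gene), , drop = FALSE]
    picks[[st]] <- utils::head(sig$gene, n_top)
    markers[[st]] <- sig
  }
  genes <- sort(unique(unlist(picks)))
  lin <- expm1(norm[, genes, drop = FALSE])
  profiles <- vapply(states, function(st) colMeans(lin[lab == st, , drop = FALSE]),
                     numeric(length(genes)))
  rownames(profiles) <- genes
  structure(list(profiles = profiles, states = states, genes = genes,
                 markers = markers), class = "SignatureMatrix")
}

#' @export
print.SignatureMatrix <- function(x, ...) {
  cat(sprintf("SignatureMatrix: %d genes x %d states (%s)\n",
              length(x$genes), length(x$states), paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Estimate cell-state fractions in bulk samples
#'
#' Per sample, solves non-negative least squares of the bulk signature-gene
#' vector against the signature matrix and renormalizes the coefficients to
#' sum to one. Estimates are invariant to global positive rescaling of a
#' bulk sample. At least half of the signature genes must be present in the
#' bulk table.
#'
#' @param bulk genes x samples matrix (TPM-like). Set `cpm = TRUE` to
#'   convert raw-count columns to counts-per-million first.
#' @param sig a [build_signature()] result.
#' @param cpm convert bulk columns to CPM before fitting (default FALSE).
#' @return object of class `FractionEstimates`: list with `fractions`
#'   (samples x states), `residual` (per-sample residual norm), `n_genes`.
#'   Use [fraction_among()] to renormalize to a subset of states (e.g.
#'   within CD8 states only).
#' @export
estimate_fractions <- function(bulk, sig, cpm = FALSE) {
  stopifnot(inherits(sig, "SignatureMatrix"))
  bulk <- as.matrix(bulk)
  if (cpm) bulk <- sweep(bulk, 2L, pmax(colSums(bulk), 1e-12), "/") * 1e6
  common <- intersect(sig$genes, rownames(bulk))
  if (length(common) < 0.5 * length(sig$genes))
    stopf("only %d/%d signature genes present in bulk; missing: %s",
          length(common), length(sig$genes),
          paste(utils::head(setdiff(sig$genes, rownames(bulk)), 5L), collapse = ", "))
  A <- sig$profiles[common, , drop = FALSE]
  n_samples <- ncol(bulk)
  fr <- matrix(NA_real_, n_samples, length(sig$states),
               dimnames = list(colnames(bulk), sig$states))
  resid <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    b <- bulk[common, j]
    if (all(b == 0)) stopf("all-zero bulk sample: %s", colnames(bulk)[j])
    fit <- pracma::lsqnonneg(A, b)
    x <- fit$x
    s <- sum(x)
    fr[j, ] <- if (s > 0) x / s else rep(1 / length(x), length(x))
    resid[j] <- sqrt(sum((A %*% x - b)^2))
  }
  structure(list(fractions = fr, residual = resid, n_genes = length(common)),
            class = "FractionEstimates")
}

#' @export
print.FractionEstimates <- function(x, ...) {
  cat(sprintf("FractionEstimates: %d sample(s) x %d state(s), %d signature genes\n",
              nrow(x$fractions), ncol(x$fractions), x$n_genes))
  print(utils::head(round(x$fractions, 4), 5L))
  invisible(x)
}

#' @export
coef.FractionEstimates <- function(object, ...) object$fractions

#' @export
residuals.FractionEstimates <- function(object, ...) object$residual

#' Renormalize fraction estimates within a subset of states
#'
#' E.g. the marker-positive share among CD8 states rather than among all
#' modeled states.
#'
#' @param est a [estimate_fractions()] result.
#' @param states character vector of states defining the denominator.
#' @return samples x states matrix renormalized to sum to 1 over `states`.
#' @export
fraction_among <- function(est, states) {
  stopifnot(inherits(est, "FractionEstimates"))
  miss <- setdiff(states, colnames(est$fractions))
  if (length(miss)) stopf("unknown state(s): %s", paste(miss, collapse = ", "))
  sub <- est$fractions[, states, drop = FALSE]
  sweep(sub, 1L, pmax(rowSums(sub), 1e-12), "/")
}
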