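# small in-code fixtures shared across test files

# dataset with explicit counts and optional metadata columns
make_ds <- function(counts, cluster = NULL, condition = NULL, normalize = FALSE,
                    ...) {
  ds <- expression_dataset(counts)
  n <- nrow(counts)
  meta <- data.frame(cell_id = rownames(ds$counts), stringsAsFactors = FALSE)
  if (!is.null(cluster)) meta$cluster <- cluster
  if (!is.null(condition)) meta$condition <- condition
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  if (ncol(meta) > 1L) ds <- attach_metadata(ds, meta)
  if (normalize) ds <- normalize_log1p(ds)
  ds
}

count_matrix <- function(n_cells, n_genes, lambda = 1, seed = 1) {
  m <- with_fixed_seed(seed, matrix(rpois(n_cells * n_genes, lambda), n_cells))
  dimnames(m) <- list(sprintf("c%03d", seq_len(n_cells)),
                      sprintf("g%03d", seq_len(n_genes)))
  m
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# one contig row with defaults
contig_row <- function(cell_id, chain = "TRB", v_gene = "TRBV1",
                       j_gene = "TRBJ1", cdr3_nt = "TGTGCAAGC",
                       cdr3_aa = "CAS", productive = TRUE, umi_count = 5L) {
  data.frame(cell_id = cell_id, chain = chain, v_gene = v_gene,
             j_gene = j_gene, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
             productive = productive, umi_count = umi_count,
             stringsAsFactors = FALSE)
}

# paired productive TRA+TRB for a cell, with a clone tag deciding the key;
# each tag character is encoded as a unique codon so distinct tags give
# distinct CDR3 sequences
paired_contigs <- function(cell_id, clone = "A", umi = 5L) {
  enc <- function(ch) {
    i <- utf8ToInt(ch) %% 64L
    paste(c("A", "C", "G", "T")[c(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L) + 1L],
          collapse = "")
  }
  nt <- paste(vapply(strsplit(clone, "")[[1]], enc, ""), collapse = "")
  nt <- paste(rep(nt, 3L), collapse = "")
  aa <- chartr("0123456789", "QRSTUVWXYZ", clone)
  rbind(contig_row(cell_id, "TRA", "TRAV1", "TRAJ1", nt, aa, TRUE, umi),
        contig_row(cell_id, "TRB", "TRBV1", "TRBJ1", nt, aa, TRUE, umi))
}

# independent entropy/expansion oracle from clone sizes
entropy_oracle <- function(sizes) {
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

# brute-force two-sided Mann-Whitney p by enumerating group assignments,
# computing U by pairwise comparison (independent of the rank-based path)
mw_oracle_p <- function(xa, xb) {
  pool <- c(xa, xb)
  nA <- length(xa); N <- length(pool)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- nA * length(xb) / 2
  uobs <- ustat(xa, xb)
  sel <- utils::combn(N, nA)
  us <- apply(sel, 2L, function(ix) ustat(pool[ix], pool[-ix]))
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
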