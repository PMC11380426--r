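#' Simulation configuration for synthetic paired scRNA + scTCR cohorts
#'
#' Defaults encode the study conditions the analysis is designed around:
#' a 2,000-cell, 500-gene, 12-cluster CD8 landscape with two planted pTRT
#' clusters (elevated tumor proportion, heavy-tailed clone sizes, elevated
#' TCR-signaling and proliferation expression), two "source" clusters that
#' receive shared pTRT clonotypes (the true pTRT-relevant cells), a
#' near-specific planted marker gene, and virus-specific clonotypes confined
#' to bystander cells with the marker suppressed.
#'
#' Clone sizes follow a truncated discrete power law; the exponent
#' difference (1.2 in pTRT clusters vs 2.0 elsewhere) and the truncation
#' bound (100 vs 50) are the clonal-expansion plant. The partition is the
#' deterministic stratified-quantile partition of that law, so the planted
#' clonality of a cluster is a stable property of its size rather than a
#' noisy draw.
#'
#' @param n_cells,n_genes,n_clusters cohort dimensions.
#' @param n_ptrt_clusters,n_source_clusters planted pTRT clusters and
#'   clonotype-sharing source clusters.
#' @param tumor_prop_ptrt,tumor_prop_other per-cluster probability that a
#'   cell comes from the tumor condition.
#' @param nb_dispersion negative-binomial size parameter of the counts.
#' @param min_gene_mean floor on the gamma-drawn base gene means; emulates
#'   post-QC data, where genes detected in only one or two cells have been
#'   removed upstream.
#' @param n_de_genes,de_fold cluster-profile plant: genes upregulated per
#'   cluster and their fold change.
#' @param signaling_base_mean,signaling_fold TCR-signaling gene expression
#'   baseline and its fold elevation in pTRT clusters.
#' @param prolif_mean_base,prolif_mean_ptrt proliferation-marker mean counts
#'   outside/inside pTRT clusters.
#' @param powerlaw_exponent_ptrt,powerlaw_exponent_other,max_clone_size_ptrt,max_clone_size_other
#'   clone-size law parameters.
#' @param sharing_rate fraction of pTRT tumor clonotypes re-seeded into
#'   source clusters.
#' @param sharing_cells_per_clone cells converted per shared clonotype.
#' @param marker_gene,marker_frac_reactive,marker_frac_bystander,marker_on_lambda
#'   planted marker: symbol, expressing fractions in true reactive vs
#'   bystander cells, and the Poisson intensity of positive counts.
#' @param n_viral_clonotypes,viral_cells_per_clonotype,viral_marker_leak
#'   virus-specific clonotype plant (confined to bystander cells; the
#'   marker fires at most at the leak rate in those cells).
#' @param tcr_capture_rate,tra_dropout_rate fraction of cells with captured
#'   TCR and, among those, the rate of missing productive TRA.
#' @param seed RNG seed; all randomness flows from it.
#' @return validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 500, n_clusters = 12,
                       n_ptrt_clusters = 2, n_source_clusters = 2,
                       tumor_prop_ptrt = 0.85, tumor_prop_other = 0.5,
                       nb_dispersion = 2, min_gene_mean = 0.05,
                       n_de_genes = 25, de_fold = 4,
                       signaling_base_mean = 0.5, signaling_fold = 3,
                       prolif_mean_base = 0.02, prolif_mean_ptrt = 0.5,
                       powerlaw_exponent_ptrt = 1.2,
                       powerlaw_exponent_other = 2.0,
                       max_clone_size_ptrt = 100, max_clone_size_other = 50,
                       sharing_rate = 0.15, sharing_cells_per_clone = 2,
                       marker_gene = "ADGRG1", marker_frac_reactive = 0.9,
                       marker_frac_bystander = 0.02, marker_on_lambda = 2,
                       n_viral_clonotypes = 5, viral_cells_per_clonotype = 20,
                       viral_marker_leak = 0.005,
                       tcr_capture_rate = 0.9, tra_dropout_rate = 0.04,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_ptrt_clusters + cfg$n_source_clusters > cfg$n_clusters)
    stopf("planted + source clusters exceed n_clusters")
  if (cfg$sharing_rate > 0 && cfg$n_source_clusters == 0)
    stopf("sharing_rate > 0 requires at least one source cluster")
  for (p in c("tumor_prop_ptrt", "tumor_prop_other", "sharing_rate",
              "marker_frac_reactive", "marker_frac_bystander",
              "viral_marker_leak", "tcr_capture_rate", "tra_dropout_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must lie in [0, 1]", p)
  if (cfg$viral_marker_leak > 0.01)
    stopf("viral_marker_leak must be <= 0.01")
  structure(cfg, class = "SimulationConfig")
}

# deterministic stratified-quantile partition of a truncated power law:
# clone sizes are the inverse CDF of p(s) ~ s^-a on 1..smax at equispaced
# probabilities, with the clone count chosen so sizes sum to n
powerlaw_partition <- function(n, a, smax) {
  if (n <= 0) return(integer(0))
  p <- (1:smax)^(-a); p <- p / sum(p)
  cdf <- cumsum(p)
  qf <- function(u) findInterval(u, cdf, left.open = TRUE) + 1L
  best <- NULL
  for (k in seq_len(n)) {
    sz <- qf((seq_len(k) - 0.5) / k)
    s <- sum(sz)
    if (is.null(best) || abs(s - n) < abs(best$s - n)) best <- list(sz = sz, s = s)
    if (s >= n && k > 5L) break
  }
  sz <- sort(best$sz, decreasing = TRUE)
  d <- n - sum(sz)
  if (d > 0) sz <- c(sz, rep(1L, d))
  while (d < 0) {
    i <- which.max(sz)
    if (sz[i] > 1L) {
      take <- min(sz[i] - 1L, -d)
      sz[i] <- sz[i] - take
      d <- d + take
    } else {
      sz <- sz[-i]
      d <- d + 1L
    }
  }
  as.integer(sort(sz[sz > 0], decreasing = TRUE))
}

sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

random_cdr3 <- function(n) {
  codons <- sense_codons()
  vapply(seq_len(n), function(i) {
    len <- sample(10:15, 1L)  # codons -> nt length 30-45, in frame
    paste(sample(codons, len, replace = TRUE), collapse = "")
  }, "")
}

translate_cdr3 <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    paste(gc[cod], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Generate a synthetic paired expression + TCR cohort with ground truth
#'
#' See [sim_config()] for the planted structure. The output contig table
#' passes [load_contigs()]-level validation and round trips through
#' [call_clonotypes()]; the ground truth records the per-cell reactivity
#' label, the planted pTRT clusters, marker and viral plants.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset` ([expression_dataset()] with
#'   metadata), `contigs` ([contig_table()]), `truth` (list).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  n <- cfg$n_cells
  ptrt_clusters <- sprintf("CD8_Temra_P%d", seq_len(cfg$n_ptrt_clusters))
  source_clusters <- sprintf("CD8_Teff_S%d", seq_len(cfg$n_source_clusters))
  n_rest <- cfg$n_clusters - cfg$n_ptrt_clusters - cfg$n_source_clusters
  rest <- sprintf("CD8_C%02d", seq_len(n_rest))
  clusters <- c(ptrt_clusters, source_clusters, rest)

  # near-even deterministic cluster sizes
  cuts <- round(seq(0, n, length.out = cfg$n_clusters + 1L))
  sizes <- diff(cuts)
  cl <- rep(clusters, times = sizes)
  cell_id <- sprintf("CELL%05d-1", seq_len(n))

  # per-cluster tumor proportions are planted exactly (stratified assignment)
  condition <- character(n)
  for (g in clusters) {
    rows <- which(cl == g)
    p <- if (g %in% ptrt_clusters) cfg$tumor_prop_ptrt else cfg$tumor_prop_other
    n_tum <- round(p * length(rows))
    tum <- sample(rows, n_tum)
    condition[tum] <- "tumor"
    condition[setdiff(rows, tum)] <- "control"
  }
  donor <- ifelse(condition == "tumor",
                  sample(paste0("P", 1:3), n, replace = TRUE),
                  sample(paste0("HD", 1:3), n, replace = TRUE))

  # gene universe: planted marker, proliferation and signaling genes plus
  # phenotype score sets, padded with filler genes
  signaling_sets <- default_tcr_signaling_sets()
  score_sets <- default_score_sets()
  prolif_genes <- c("MKI67", "TOP2A", "PCNA")
  special <- unique(c(cfg$marker_gene, prolif_genes, unlist(signaling_sets),
                      unlist(score_sets)))
  if (cfg$n_genes <= length(special))
    stopf("n_genes must exceed the %d built-in genes", length(special))
  fillers <- sprintf("GENE%04d", seq_len(cfg$n_genes - length(special)))
  genes <- c(special, fillers)

  # gamma-distributed base means, floored at the detection scale upstream QC
  # retains (post-QC matrices carry no genes seen in only one or two cells)
  base_mu <- pmax(stats::rgamma(cfg$n_genes, shape = 0.8, rate = 4),
                  cfg$min_gene_mean)
  names(base_mu) <- genes
  base_mu[intersect(unlist(signaling_sets), genes)] <- cfg$signaling_base_mean
  base_mu[prolif_genes] <- cfg$prolif_mean_base
  base_mu[cfg$marker_gene] <- 0

  de_genes <- lapply(clusters, function(g)
    sample(fillers, min(cfg$n_de_genes, length(fillers))))
  names(de_genes) <- clusters

  counts <- matrix(0, n, cfg$n_genes, dimnames = list(cell_id, genes))
  signaling_genes <- intersect(unlist(signaling_sets), genes)
  for (g in clusters) {
    rows <- which(cl == g)
    mu <- base_mu
    mu[de_genes[[g]]] <- mu[de_genes[[g]]] * cfg$de_fold
    if (g %in% ptrt_clusters) {
      mu[signaling_genes] <- mu[signaling_genes] * cfg$signaling_fold
      mu[prolif_genes] <- cfg$prolif_mean_ptrt
    }
    counts[rows, ] <- stats::rnbinom(length(rows) * cfg$n_genes,
                                     size = cfg$nb_dispersion,
                                     mu = rep(mu, each = length(rows)))
  }

  # clonotype structure: separate clone pools per (cluster, condition);
  # the tumor pool of a pTRT cluster carries the heavy-tailed law
  clone_of <- character(n)
  for (g in clusters) {
    is_ptrt <- g %in% ptrt_clusters
    a <- if (is_ptrt) cfg$powerlaw_exponent_ptrt else cfg$powerlaw_exponent_other
    smax <- if (is_ptrt) cfg$max_clone_size_ptrt else cfg$max_clone_size_other
    for (cond in c("tumor", "control")) {
      rows <- which(cl == g & condition == cond)
      if (!length(rows)) next
      aa <- if (cond == "tumor") a else cfg$powerlaw_exponent_other
      ss <- if (cond == "tumor") smax else cfg$max_clone_size_other
      part <- powerlaw_partition(length(rows), aa, ss)
      ids <- sprintf("%s_%s_cl%03d", g, cond, seq_along(part))
      clone_of[sample(rows)] <- rep(ids, times = part)
    }
  }

  # re-seed a share of pTRT tumor clonotypes into source clusters
  relevant <- logical(n)
  ptrt_tumor_cts <- unique(clone_of[cl %in% ptrt_clusters & condition == "tumor"])
  n_share <- round(cfg$sharing_rate * length(ptrt_tumor_cts))
  shared_cts <- if (n_share > 0) sample(ptrt_tumor_cts, n_share) else character(0)
  if (length(shared_cts)) {
    pool <- which(cl %in% source_clusters & condition == "tumor")
    pool <- sample(pool)
    used <- 0L
    for (ctid in shared_cts) {
      take <- min(cfg$sharing_cells_per_clone, length(pool) - used)
      if (take <= 0L) break
      sel <- pool[used + seq_len(take)]
      clone_of[sel] <- ctid
      relevant[sel] <- TRUE
      used <- used + take
    }
  }

  # viral clonotypes confined to bystander cells
  viral <- logical(n)
  viral_ct_names <- character(0)
  if (cfg$n_viral_clonotypes > 0) {
    bys <- which(!(cl %in% ptrt_clusters) & !relevant)
    need <- cfg$n_viral_clonotypes * cfg$viral_cells_per_clonotype
    if (length(bys) < need) stopf("not enough bystander cells for the viral plant")
    sel <- sample(bys, need)
    viral_ct_names <- sprintf("viral_cl%02d", seq_len(cfg$n_viral_clonotypes))
    clone_of[sel] <- rep(viral_ct_names, each = cfg$viral_cells_per_clonotype)
    viral[sel] <- TRUE
  }

  truth_label <- ifelse(cl %in% ptrt_clusters, "pTRT",
                        ifelse(relevant, "pTRT-relevant", "pTRT-irrelevant"))
  reactive <- truth_label != "pTRT-irrelevant"

  # planted marker expression
  p_on <- ifelse(reactive, cfg$marker_frac_reactive, cfg$marker_frac_bystander)
  p_on[viral] <- cfg$viral_marker_leak
  on <- stats::rbinom(n, 1L, p_on) == 1L
  counts[, cfg$marker_gene] <- ifelse(on, stats::rpois(n, cfg$marker_on_lambda) + 1L, 0L)

  # paired chains per clonotype
  cts <- unique(clone_of)
  chains <- data.frame(
    clonotype = cts,
    tra_v = sample(sprintf("TRAV%d", 1:20), length(cts), replace = TRUE),
    tra_j = sample(sprintf("TRAJ%d", 1:40), length(cts), replace = TRUE),
    trb_v = sample(sprintf("TRBV%d", 1:20), length(cts), replace = TRUE),
    trb_j = sample(sprintf("TRBJ%d", 1:12), length(cts), replace = TRUE),
    tra_cdr3_nt = random_cdr3(length(cts)),
    trb_cdr3_nt = random_cdr3(length(cts)),
    stringsAsFactors = FALSE)
  chains$tra_cdr3_aa <- translate_cdr3(chains$tra_cdr3_nt)
  chains$trb_cdr3_aa <- translate_cdr3(chains$trb_cdr3_nt)

  captured <- stats::rbinom(n, 1L, cfg$tcr_capture_rate) == 1L
  captured[relevant | viral] <- TRUE
  tra_drop <- stats::rbinom(n, 1L, cfg$tra_dropout_rate) == 1L & !(relevant | viral)

  idx <- match(clone_of, chains$clonotype)
  mk_rows <- function(which_cells, chain) {
    i <- idx[which_cells]
    if (chain == "TRA")
      data.frame(cell_id = cell_id[which_cells], chain = "TRA",
                 v_gene = chains$tra_v[i], j_gene = chains$tra_j[i],
                 cdr3_nt = chains$tra_cdr3_nt[i], cdr3_aa = chains$tra_cdr3_aa[i],
                 productive = TRUE,
                 umi_count = stats::rpois(length(i), 4) + 1L,
                 stringsAsFactors = FALSE)
    else
      data.frame(cell_id = cell_id[which_cells], chain = "TRB",
                 v_gene = chains$trb_v[i], j_gene = chains$trb_j[i],
                 cdr3_nt = chains$trb_cdr3_nt[i], cdr3_aa = chains$trb_cdr3_aa[i],
                 productive = TRUE,
                 umi_count = stats::rpois(length(i), 4) + 1L,
                 stringsAsFactors = FALSE)
  }
  cap_cells <- which(captured)
  rows_tra <- mk_rows(cap_cells[!tra_drop[cap_cells]], "TRA")
  rows_trb <- mk_rows(cap_cells, "TRB")
  # a small admixture of nonproductive secondary TRB contigs
  extra_cells <- cap_cells[stats::rbinom(length(cap_cells), 1L, 0.03) == 1L]
  rows_extra <- if (length(extra_cells)) {
    nt <- random_cdr3(length(extra_cells))
    data.frame(cell_id = cell_id[extra_cells], chain = "TRB",
               v_gene = sample(sprintf("TRBV%d", 1:20), length(extra_cells), TRUE),
               j_gene = sample(sprintf("TRBJ%d", 1:12), length(extra_cells), TRUE),
               cdr3_nt = nt, cdr3_aa = translate_cdr3(nt),
               productive = FALSE, umi_count = 1L, stringsAsFactors = FALSE)
  } else NULL
  contigs <- contig_table(rbind(rows_tra, rows_trb, rows_extra))

  meta <- data.frame(cell_id = cell_id, cluster = cl, condition = condition,
                     donor = donor, compartment = "CD8",
                     stringsAsFactors = FALSE)
  ds <- expression_dataset(counts, cell_meta = meta)

  truth <- list(
    cell_labels = setNames(truth_label, cell_id),
    ptrt_clusters = ptrt_clusters,
    source_clusters = source_clusters,
    marker_gene = cfg$marker_gene,
    marker_frac_reactive = cfg$marker_frac_reactive,
    marker_frac_bystander = cfg$marker_frac_bystander,
    viral_marker_leak = cfg$viral_marker_leak,
    viral_clonotypes = viral_ct_names,
    viral_cells = cell_id[viral],
    relevant_cells = cell_id[relevant],
    viral_reference = data.frame(
      cdr3_aa_beta = chains$trb_cdr3_aa[match(viral_ct_names, chains$clonotype)],
      v_gene = chains$trb_v[match(viral_ct_names, chains$clonotype)],
      species = "synthetic-virus", stringsAsFactors = FALSE),
    config = unclass(cfg))
  list(dataset = ds, contigs = contigs, truth = truth)
}

#' Closed-form planted precision of the synthetic marker
#'
#' Expected reactive-cell precision implied by the planted expressing
#' fractions and the realized group sizes:
#' `fr * nR / (fr * nR + fb * (nB - nV) + leak * nV)`.
#'
#' @param truth the `truth` element of [generate_dataset()] output.
#' @return expected precision in `[0, 1]`.
#' @export
planted_marker_precision <- function(truth) {
  lab <- truth$cell_labels
  nR <- sum(lab != "pTRT-irrelevant")
  nV <- length(truth$viral_cells)
  nB <- sum(lab == "pTRT-irrelevant")
  fr <- truth$marker_frac_reactive
  fb <- truth$marker_frac_bystander
  leak <- truth$viral_marker_leak
  fr * nR / (fr * nR + fb * (nB - nV) + leak * nV)
}

#' Generate synthetic bulk mixtures with known fractions
#'
#' Per sample, fractions are drawn from a Dirichlet (or supplied directly),
#' state profiles are mixed linearly, and multiplicative lognormal noise is
#' applied per gene.
#'
#' @param profiles genes x states matrix of state expression profiles
#'   (e.g. `build_signature(...)$profiles`).
#' @param n_samples number of mixtures (default 20).
#' @param dirichlet_alpha Dirichlet concentration, scalar or per-state
#'   vector (default 1).
#' @param noise_sigma lognormal sigma of the multiplicative noise
#'   (default 0.2; 0 = noiseless).
#' @param fractions optional n_samples x states matrix overriding the
#'   Dirichlet draw (rows must sum to 1).
#' @param seed RNG seed.
#' @return list with `bulk` (genes x samples), `fractions` (truth,
#'   samples x states).
#' @export
generate_bulk_mixtures <- function(profiles, n_samples = 20,
                                   dirichlet_alpha = 1, noise_sigma = 0.2,
                                   fractions = NULL, seed = 1) {
  profiles <- as.matrix(profiles)
  k <- ncol(profiles)
  if (k < 2L) stopf("need >= 2 states")
  alpha <- rep_len(dirichlet_alpha, k)
  if (any(alpha <= 0)) stopf("dirichlet_alpha must be positive")
  with_seed(seed, {
    if (is.null(fractions)) {
      g <- matrix(stats::rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                  n_samples, k)
      fractions <- g / rowSums(g)
    } else {
      fractions <- as.matrix(fractions)
      stopifnot(ncol(fractions) == k)
      n_samples <- nrow(fractions)
    }
    colnames(fractions) <- colnames(profiles)
    rownames(fractions) <- sprintf("S%02d", seq_len(n_samples))
    bulk <- profiles %*% t(fractions)
    if (noise_sigma > 0)
      bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, noise_sigma),
                                nrow(bulk), ncol(bulk)))
    colnames(bulk) <- rownames(fractions)
    list(bulk = bulk, fractions = fractions)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the MTX directory (with per-cell metadata), a 10x-style contig CSV,
#' the ground-truth JSON and a copy of the configuration — the on-disk form
#' consumed by [run_pipeline()].
#'
#' @param sim a [generate_dataset()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(sim$dataset, file.path(dir, "counts"))
  ct <- sim$contigs
  tenx <- data.frame(barcode = ct$cell_id, chain = ct$chain,
                     v_gene = ct$v_gene, j_gene = ct$j_gene,
                     cdr3_nt = ct$cdr3_nt, cdr3 = ct$cdr3_aa,
                     productive = ifelse(ct$productive, "true", "false"),
                     umis = ct$umi_count, stringsAsFactors = FALSE)
  utils::write.csv(tenx, file.path(dir, "contigs.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- sim$truth
  truth$viral_reference <- as.list(truth$viral_reference)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(sim$truth$config, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
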