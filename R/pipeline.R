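#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates load -> normalize -> clonotypes -> cluster indices -> pTRT
#' call -> reactivity labels -> marker ranking -> optional viral exclusion
#' -> optional deconvolution, writing all result tables and a run report to
#' the output directory. Results are staged and moved into place so a failed
#' run leaves no partial output directory behind.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' fields:
#' \preformatted{
#' input:
#'   counts: path            # MTX directory or dense TSV
#'   counts_format: mtx_dir  # or dense_tsv
#'   contigs: path           # contig file
#'   contigs_dialect: tenx_csv  # or airr_tsv
#'   metadata: path          # optional cell_meta TSV (cell_id column)
#' params:
#'   scale_total: 10000
#'   n_bins: 25
#'   n_ctrl: 50
#'   tau_enrichment: 1.2
#'   tau_expansion: 0.2
#'   tau_proliferation: 0.05
#'   tau_signaling: 0
#'   min_tumor_cells: 20
#'   tumor_level: tumor
#'   bystander_mean_cutoff: 0.5
#'   top_k: 100
#'   marker_gene: ADGRG1
#'   seed: 0
#' signaling_gmt: path       # optional, defaults to built-in sets
#' viral_reference: path     # optional TSV (cdr3_aa_beta, v_gene, species)
#' bulk: path                # optional bulk TSV -> deconvolution stage
#' deconv_states: reactivity # or a cell_meta column name
#' }
#'
#' @param config path to a YAML config or a named list.
#' @param out_dir output directory.
#' @return the run report (class `ptrt_report`), invisibly writing
#'   `cluster_indices.tsv`, `reactivity_labels.tsv`, `marker_ranking.tsv`,
#'   optional `viral_flags.tsv` and `deconvolution.tsv`, plus
#'   `run_report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  p <- pipeline_params(cfg$params %||% list())
  stage <- "load"
  report <- list(config = cfg, seed = p$seed,
                 version = as.character(utils::packageVersion("ptrtkit")),
                 stages = list())
  t0 <- proc.time()[[3L]]
  tick <- function(name) {
    t1 <- proc.time()[[3L]]
    report$stages[[name]]$seconds <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  res <- tryCatch({
    ds <- load_counts(cfg$input$counts, cfg$input$counts_format %||% "mtx_dir")
    if (!is.null(cfg$input$metadata)) {
      meta <- utils::read.delim(cfg$input$metadata, stringsAsFactors = FALSE)
      ds <- attach_metadata(ds, meta, strict = FALSE)
    }
    contigs <- load_contigs(cfg$input$contigs,
                            cfg$input$contigs_dialect %||% "tenx_csv")
    report$stages$load <- list(cells = nrow(ds$counts), genes = ncol(ds$counts),
                               contig_rows = nrow(contigs),
                               dropped_loci = attr(contigs, "dropped_loci"))
    tick("load")

    stage <- "fit"
    sig_sets <- if (!is.null(cfg$signaling_gmt)) read_gmt(cfg$signaling_gmt)
                else default_tcr_signaling_sets()
    fit <- ptrt(ds, contigs, signaling_sets = sig_sets,
                tumor_level = p$tumor_level,
                min_tumor_cells = p$min_tumor_cells,
                n_bins = p$n_bins, n_ctrl = p$n_ctrl,
                tau_enrichment = p$tau_enrichment,
                tau_expansion = p$tau_expansion,
                tau_proliferation = p$tau_proliferation,
                tau_signaling = p$tau_signaling,
                scale_total = p$scale_total, seed = p$seed)
    tal <- table(unclass(fit$labels))
    report$stages$fit <- list(
      assigned_cells = nrow(fit$clonotypes$cells),
      unassigned_cells = nrow(fit$clonotypes$unassigned),
      clonotypes = nrow(fit$clonotypes$clonotypes),
      ptrt_clusters = fit$ptrt_clusters,
      label_tally = as.list(setNames(as.integer(tal), names(tal))))
    tick("fit")

    stage <- "markers"
    ranking <- rank_marker_candidates(fit$dataset, fit$labels,
                                      bystander_mean_cutoff = p$bystander_mean_cutoff,
                                      top_k = p$top_k)
    top <- ranking[!is.na(ranking$rank), ]
    top <- top[order(top$rank), ]
    report$stages$markers <- list(
      candidates = sum(ranking$candidate),
      top_gene = if (nrow(top)) top$gene[1L] else NA_character_,
      top_precision = if (nrow(top)) top$precision[1L] else NA_real_)
    tick("markers")

    viral <- NULL
    if (!is.null(cfg$viral_reference)) {
      stage <- "viral"
      ref <- utils::read.delim(cfg$viral_reference, stringsAsFactors = FALSE)
      viral <- flag_viral_clonotypes(fit$clonotypes, ref)
      report$stages$viral <- list(
        flagged_cells = sum(viral$viral_tcr),
        marker_fraction = if (any(viral$viral_tcr))
          marker_expression_in_viral(fit$dataset, viral, p$marker_gene)
        else NA_real_)
      tick("viral")
    }

    deconv <- NULL
    if (!is.null(cfg$bulk)) {
      stage <- "deconvolution"
      bulk <- load_bulk(cfg$bulk)
      states <- deconv_state_labels(fit, cfg$deconv_states %||% "reactivity",
                                    p$marker_gene)
      sig <- build_signature(fit$dataset, states)
      deconv <- estimate_fractions(bulk, sig)
      report$stages$deconvolution <- list(states = sig$states,
                                          samples = nrow(deconv$fractions),
                                          signature_genes = length(sig$genes))
      tick("deconvolution")
    }

    stage <- "write"
    write_pipeline_outputs(out_dir, fit, ranking, viral, deconv, report)
    report$stages$write <- list(out_dir = out_dir)
    tick("write")
    structure(report, class = "ptrt_report")
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}

pipeline_params <- function(p) {
  defaults <- list(scale_total = 1e4, n_bins = 25, n_ctrl = 50,
                   tau_enrichment = 1.2, tau_expansion = 0.2,
                   tau_proliferation = 0.05, tau_signaling = 0,
                   min_tumor_cells = 20, tumor_level = "tumor",
                   bystander_mean_cutoff = 0.5, top_k = 100,
                   marker_gene = "ADGRG1", seed = 0)
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown)) stopf("unknown config params: %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, p)
}

validate_config <- function(cfg) {
  if (is.null(cfg$input)) stopf("config validation: missing field 'input'")
  for (f in c("counts", "contigs")) {
    if (is.null(cfg$input[[f]]))
      stopf("config validation: missing field 'input.%s'", f)
    if (!file.exists(cfg$input[[f]]) && !dir.exists(cfg$input[[f]]))
      stopf("config validation: input.%s path not found: %s", f, cfg$input[[f]])
  }
  invisible(TRUE)
}

deconv_state_labels <- function(fit, mode, marker_gene) {
  ds <- fit$dataset
  if (mode == "reactivity") {
    # marker-positive CD8 state carved out of the reactivity labels
    pos <- ds$counts[, marker_gene] > 0
    comp <- ds$cell_meta$compartment
    ifelse(comp %in% "CD8" & pos, paste0(marker_gene, "pos_CD8"),
           ifelse(unclass(fit$labels) == "pTRT-irrelevant",
                  "bystander", "reactive_markerneg"))
  } else {
    v <- ds$cell_meta[[mode]]
    if (is.null(v)) stopf("unknown deconv_states column: %s", mode)
    as.character(v)
  }
}

write_pipeline_outputs <- function(out_dir, fit, ranking, viral, deconv, report) {
  staging <- tempfile("ptrt_stage_")
  dir.create(staging, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(staging, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  idx <- fit$indices
  attr(idx, "thresholds") <- NULL
  wt(idx, "cluster_indices.tsv")
  wt(data.frame(cell_id = names(fit$labels), label = unclass(fit$labels),
                stringsAsFactors = FALSE), "reactivity_labels.tsv")
  wt(as.data.frame(ranking), "marker_ranking.tsv")
  if (!is.null(viral)) wt(as.data.frame(viral), "viral_flags.tsv")
  if (!is.null(deconv))
    wt(cbind(sample = rownames(deconv$fractions),
             as.data.frame(deconv$fractions),
             residual = deconv$residual), "deconvolution.tsv")
  rep_out <- report
  rep_out$stages <- lapply(rep_out$stages, function(s) { s$seconds <- NULL; s })
  jsonlite::write_json(rep_out, file.path(staging, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  invisible(out_dir)
}

#' @export
print.ptrt_report <- function(x, ...) {
  cat("ptrt pipeline report (version", x$version, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                paste(sprintf("%s=%s", names(s),
                              vapply(s, function(v) paste(format(v), collapse = ","), "")),
                      collapse = "  ")))
  }
  invisible(x)
}
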