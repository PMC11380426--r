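#' Gene set collections
#'
#' A gene set collection is a named list of unique gene symbol vectors with a
#' per-set provenance note (`attr(x, "provenance")`).
#'
#' @param sets named list of character vectors.
#' @param provenance optional named character vector of provenance notes.
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stopf("every gene set must be named")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stopf("empty gene set not allowed")
  structure(sets, class = "GeneSetCollection",
            provenance = provenance %||% setNames(rep("unspecified", length(sets)),
                                                  names(sets)))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("malformed GMT line(s): %s", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  prov <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  gene_set_collection(sets, prov)
}

#' Write gene sets to a GMT file
#' @param sets a [gene_set_collection()] or named list.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  prov <- attr(sets, "provenance") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, prov[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Default phenotype scoring gene sets
#'
#' Editable defaults for naive / cytotoxicity / exhaustion / senescence
#' scores. These are standard T-cell phenotype markers, not an authoritative
#' reproduction of any published supplement; replace with your own GMT
#' for exact comparisons.
#'
#' @return a [gene_set_collection()].
#' @export
default_score_sets <- function() {
  gene_set_collection(list(
    naive = c("CCR7", "TCF7", "LEF1", "SELL", "IL7R"),
    cytotoxicity = c("GZMB", "PRF1", "GNLY", "NKG7", "IFNG", "KLRG1"),
    exhaustion = c("PDCD1", "TOX", "LAG3", "HAVCR2", "CTLA4", "TIGIT"),
    senescence = c("B3GAT1", "KLRG1", "CDKN1A", "CDKN2A")
  ), provenance = c(naive = "package default", cytotoxicity = "package default",
                    exhaustion = "package default", senescence = "package default"))
}

#' Default TCR-signaling gene sets
#'
#' Six compact TCR-signaling pathway sets used for the per-cluster
#' TCR-activation index (proximal signaling, downstream signaling, CD3/TCR
#' zeta phosphorylation, second-messenger generation, the TCR-alpha pathway
#' and ZAP70 synapse translocation). Shipped as editable defaults; swap in
#' MSigDB exports via [read_gmt()] for exact pathway membership.
#'
#' @return a [gene_set_collection()].
#' @export
default_tcr_signaling_sets <- function() {
  gene_set_collection(list(
    TCR_signaling = c("CD3D", "CD3E", "CD3G", "CD247", "LCK", "FYN", "ZAP70", "LAT"),
    Downstream_TCR_signaling = c("NFKB1", "NFATC2", "RELA", "MAP3K8", "CARD11",
                                 "BCL10", "MALT1", "PRKCQ"),
    pCD3_and_TCRZ = c("CD3D", "CD3E", "CD3G", "CD247", "LCK", "PTPRC"),
    Second_messenger = c("LAT", "LCP2", "PLCG1", "ITK", "VAV1", "GRB2", "SOS1"),
    TCRa_pathway = c("CD3E", "CD28", "PTPRC", "ZAP70", "LCK", "CSK"),
    ZAP70_to_immunosynapse = c("ZAP70", "CD3D", "CD3E", "CD3G", "CD247", "FYN")
  ), provenance = setNames(rep("package default", 6L),
                           c("TCR_signaling", "Downstream_TCR_signaling",
                             "pCD3_and_TCRZ", "Second_messenger",
                             "TCRa_pathway", "ZAP70_to_immunosynapse")))
}

#' Published cohort cell counts used as reference anchors
#'
#' Post-QC cell counts of the three study cohorts this package's workflow was
#' designed around: the human AML + healthy-donor T-cell integration, the
#' conditional fusion-gene mouse experiment, and the AML/MDS + healthy-donor
#' CD8 integration. `cells` holds the per-group counts, `total` the printed
#' integrated total; [check_count_consistency()] verifies that groups sum to
#' totals.
#'
#' @return data.frame with columns `cohort`, `group`, `cells`, `total`.
#' @export
study_cell_counts <- function() {
  data.frame(
    cohort = c("human_integration", "human_integration",
               "mouse_experiment", "mouse_experiment",
               "aml_mds_integration", "aml_mds_integration"),
    group = c("AML_patients", "healthy_donors",
              "control_group", "fusion_group",
              "AML_MDS_patients", "healthy_donors"),
    cells = c(25868L, 31318L, 21410L, 22040L, 18237L, 5417L),
    total = c(57186L, 57186L, 43450L, 43450L, 23654L, 23654L),
    stringsAsFactors = FALSE
  )
}

#' Check per-group cell counts against cohort totals
#'
#' @param counts a data.frame as returned by [study_cell_counts()].
#' @return data.frame with one row per cohort: the group sum, the stated
#'   total and a `consistent` flag.
#' @export
check_count_consistency <- function(counts = study_cell_counts()) {
  sums <- tapply(counts$cells, counts$cohort, sum)
  totals <- tapply(counts$total, counts$cohort, function(x) unique(x)[1L])
  data.frame(cohort = names(sums),
             group_sum = as.integer(sums),
             total = as.integer(totals[names(sums)]),
             consistent = as.integer(sums) == as.integer(totals[names(sums)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
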