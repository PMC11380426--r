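#' Construct a TCR contig table
#'
#' One row per assembled chain: cell barcode, locus (TRA/TRB), V and J gene
#' calls, nucleotide and amino-acid CDR3, productivity flag and UMI support.
#'
#' @param df data.frame with columns `cell_id`, `chain`, `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `productive`, `umi_count`.
#' @return a validated data.frame of class `ContigTable`.
#' @export
contig_table <- function(df) {
  req <- c("cell_id", "chain", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa",
           "productive", "umi_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("contig table missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[, req]
  df$cell_id <- as.character(df$cell_id)
  df$chain <- as.character(df$chain)
  df$cdr3_nt <- toupper(as.character(df$cdr3_nt))
  df$cdr3_aa <- toupper(as.character(df$cdr3_aa))
  if (!all(df$chain %in% c("TRA", "TRB")))
    stopf("chain must be TRA or TRB (got: %s)",
          paste(utils::head(setdiff(unique(df$chain), c("TRA", "TRB")), 3L), collapse = ", "))
  if (any(!grepl("^[ACGTN]*$", df$cdr3_nt)))
    stopf("cdr3_nt contains non-DNA characters")
  if (any(!grepl("^[A-Z*]*$", df$cdr3_aa)))
    stopf("cdr3_aa contains non-amino-acid characters")
  df$productive <- as.logical(df$productive)
  df$umi_count <- as.integer(df$umi_count)
  if (anyNA(df$umi_count) || any(df$umi_count < 0))
    stopf("umi_count must be a non-negative integer")
  class(df) <- c("ContigTable", "data.frame")
  df
}

# 10x truth strings for the `productive` field
tenx_truthy <- function(x) tolower(trimws(as.character(x))) %in% "true"

#' Load TCR contigs from 10x or AIRR files
#'
#' Supports the 10x Cell Ranger `filtered_contig_annotations.csv` dialect and
#' the AIRR rearrangement TSV schema (which also covers TRUST4-style bulk
#' reports exported in AIRR format). Loci other than TRA/TRB (e.g. TRG/TRD)
#' are dropped with a counted warning; the count is available as
#' `attr(x, "dropped_loci")`.
#'
#' @param path input file.
#' @param dialect `"tenx_csv"` or `"airr_tsv"`.
#' @return a [contig_table()] with attribute `dropped_loci`.
#' @export
load_contigs <- function(path, dialect = c("tenx_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "tenx_csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt", "cdr3",
             "productive", "umis")
    miss <- setdiff(req, names(raw))
    if (length(miss)) stopf("10x contig file missing column(s): %s",
                            paste(miss, collapse = ", "))
    df <- data.frame(cell_id = raw$barcode, chain = raw$chain,
                     v_gene = raw$v_gene, j_gene = raw$j_gene,
                     cdr3_nt = raw$cdr3_nt, cdr3_aa = raw$cdr3,
                     productive = tenx_truthy(raw$productive),
                     umi_count = raw$umis, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("cell_id", "locus", "v_call", "j_call", "junction",
             "junction_aa", "productive", "duplicate_count")
    miss <- setdiff(req, names(raw))
    if (length(miss)) stopf("AIRR file missing column(s): %s",
                            paste(miss, collapse = ", "))
    df <- data.frame(cell_id = raw$cell_id, chain = raw$locus,
                     v_gene = raw$v_call, j_gene = raw$j_call,
                     cdr3_nt = raw$junction, cdr3_aa = raw$junction_aa,
                     productive = toupper(trimws(as.character(raw$productive))) %in% c("T", "TRUE"),
                     umi_count = raw$duplicate_count, stringsAsFactors = FALSE)
  }
  keep <- df$chain %in% c("TRA", "TRB")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    warnf("dropped %d contig(s) with non-TRA/TRB locus", n_drop)
  out <- contig_table(df[keep, , drop = FALSE])
  attr(out, "dropped_loci") <- n_drop
  out
}
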