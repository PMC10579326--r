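#' Validate a gene count table
#'
#' A gene count table has one row per representative sequence (clustering
#' is upstream) with columns `gene_id`, `orf_length` (bp, > 0),
#' `read_count` (mapped reads already filtered at > 80% identity, >= 0),
#' `taxon_label` and `gene_family` (one of `"phnJ"`, `"recA"`, `"other"`).
#'
#' @param table data.frame to validate.
#' @return The table, invisibly, after checks.
#' @keywords internal
check_gene_table <- function(table) {
  req <- c("gene_id", "orf_length", "read_count", "gene_family")
  if (!all(req %in% names(table))) {
    stop("gene count table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$orf_length <= 0)) stop("orf_length must be > 0", call. = FALSE)
  if (any(table$read_count < 0)) stop("read_count must be >= 0", call. = FALSE)
  invisible(table)
}

#' Transcripts/fragments per million (TPM)
#'
#' Length-normalized relative abundance: per-gene read rate
#' `rate_i = count_i / length_i`, scaled so the table sums to 10^6. The
#' same arithmetic serves metagenomic and metatranscriptomic counts.
#'
#' @param table A gene count table (see [check_gene_table()]).
#' @return The table with a `tpm` column added (sums to 10^6).
#' @export
tpm <- function(table) {
  check_gene_table(table)
  if (all(table$read_count == 0)) {
    stop("undefined TPM: all read counts are zero", call. = FALSE)
  }
  rate <- table$read_count / table$orf_length
  table$tpm <- rate / sum(rate) * 1e6
  table
}

#' phnJ relative abundance normalized to the single-copy gene recA
#'
#' Expresses the phosphonate-utilisation marker as a percentage of
#' genomes: length-normalized phnJ counts divided by length-normalized
#' recA counts (recA assumed single-copy per bacterium), times 100. phnJ
#' clusters are length-normalized individually and then summed.
#'
#' @param table A gene count table containing `phnJ` and `recA` rows.
#' @return Percentage of genomes carrying phnJ (may exceed 100 if the
#'   marker outnumbers the single-copy gene signal).
#' @export
phnj_relative_abundance <- function(table) {
  check_gene_table(table)
  rate <- table$read_count / table$orf_length
  reca <- sum(rate[table$gene_family == "recA"])
  if (reca <= 0) {
    stop("undefined abundance: no recA signal", call. = FALSE)
  }
  100 * sum(rate[table$gene_family == "phnJ"]) / reca
}

#' Apply the mapping identity filter and aggregate counts per gene
#'
#' Input contract for tables built from raw mapping hits: rows with a
#' percent identity at or below the threshold (strictly greater than 80
#' retained, by default) are discarded, and surviving read counts are
#' summed per gene.
#'
#' @param raw_hits data.frame with columns `gene_id`, `orf_length`,
#'   `percent_identity` (in [0, 100]), optional `read_count` (default 1
#'   per row), `taxon_label`, `gene_family`.
#' @param threshold Identity threshold, percent (default 80, strict `>`).
#' @return A gene count table with one row per gene and aggregated
#'   `read_count`.
#' @export
identity_filter <- function(raw_hits, threshold = 80) {
  if (!nrow(raw_hits)) {
    return(data.frame(gene_id = character(), orf_length = numeric(),
                      read_count = numeric(), taxon_label = character(),
                      gene_family = character(), stringsAsFactors = FALSE))
  }
  if (any(raw_hits$percent_identity < 0 | raw_hits$percent_identity > 100)) {
    stop("percent_identity must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(raw_hits$read_count)) raw_hits$read_count <- 1
  keep <- raw_hits[raw_hits$percent_identity > threshold, , drop = FALSE]
  if (!nrow(keep)) {
    return(data.frame(gene_id = character(), orf_length = numeric(),
                      read_count = numeric(), taxon_label = character(),
                      gene_family = character(), stringsAsFactors = FALSE))
  }
  counts <- tapply(keep$read_count, keep$gene_id, sum)
  first <- keep[!duplicated(keep$gene_id), , drop = FALSE]
  first <- first[order(first$gene_id), , drop = FALSE]
  out <- data.frame(
    gene_id = names(counts),
    orf_length = first$orf_length,
    read_count = as.numeric(counts),
    taxon_label = if ("taxon_label" %in% names(first)) first$taxon_label
                  else NA_character_,
    gene_family = if ("gene_family" %in% names(first)) first$gene_family
                  else "other",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a gene count table from TSV/CSV
#'
#' @param path File with columns `gene_id`, `orf_length`, `read_count`,
#'   `taxon_label`, `gene_family`.
#' @return Validated gene count table.
#' @export
read_gene_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  check_gene_table(tab)
  tab
}
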