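#' Read a posterior-summary expression table
#'
#' Tab-separated with columns `transcript_id`, `sample_id`,
#' `mean_log_expr`, `sd_log_expr` (the quantifier's posterior mean and SD
#' of log expression per transcript and sample).
#'
#' @param path file path.
#' @return `data.frame` in the expected column order.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "sample_id", "mean_log_expr", "sd_log_expr")
  if (!all(need %in% names(df)))
    stop_bad_arg(path, ": expected columns ", paste(need, collapse = ", "))
  df[need]
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample_id`, `condition`, `fraction`,
#' `replicate`; validated through [sample_design()].
#'
#' @param path file path.
#' @return A validated design `data.frame`.
#' @export
read_design_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "fraction", "replicate")
  if (!all(need %in% names(df)))
    stop_bad_arg(path, ": expected columns ", paste(need, collapse = ", "))
  sample_design(df$condition, df$fraction, df$replicate, df$sample_id)
}

#' Read a transcript-to-gene map
#'
#' Two tab-separated columns: `transcript_id`, `gene_id`.
#'
#' @param path file path.
#' @return `data.frame` with the two columns.
#' @export
read_gene_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(df)))
    stop_bad_arg(path, ": expected columns transcript_id, gene_id")
  df[c("transcript_id", "gene_id")]
}

#' Read 5'UTR sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of normalized sequences.
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  # FASTA headers may carry descriptions; keep the first token as the id
  names(seqs) <- sub("\\s.*$", "", names(x))
  normalize_seq(seqs)
}

#' Write sequences to FASTA
#'
#' @param seq named character vector.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(seq, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seq), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a preranked gene list (.rnk)
#'
#' Two tab-separated columns without header (gene id, rank score), sorted
#' by decreasing score, the layout preranked enrichment tools expect.
#'
#' @param gene_id character vector.
#' @param score numeric scores (e.g. [rank_metric()] output).
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(gene_id, score, path) {
  ord <- order(-score, gene_id)
  write.table(data.frame(gene_id[ord], score[ord]), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
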