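# File-format plumbing: TSV is the interchange dialect (tab-separated, header
# row, UTF-8, '.' decimal), FASTA for sequences, JSON for summaries and
# ground-truth sidecars.

#' Read a tab-separated table
#'
#' @param path File path.
#' @param required_cols Character vector of column names that must be present.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a tab-separated table
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a transcript set from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences (names = ids).
#' @export
read_transcripts_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a transcript set to FASTA
#'
#' @param transcripts Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  ss <- Biostrings::DNAStringSet(transcripts)
  names(ss) <- names(transcripts)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene-set file (one id per line)
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write a gene set (one id per line)
#'
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# reverse complement over {A,C,G,T,N}; base chartr keeps the mapping hot-loop
# cheap compared to DNAString round trips
rev_comp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
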