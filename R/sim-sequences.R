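# Sequence-level generators: transcript set and paired-end tags with
# provenance labels. Each generator derives its RNG stream from the config
# seed plus a fixed offset, so a given config is byte-reproducible.

#' Generate a synthetic transcript set
#'
#' Transcripts are uniform random sequences over A/C/G/T (GC fraction 0.5 in
#' expectation), standing in for a small mRNA reference at toy scale.
#'
#' @param config A [sim_config()].
#' @return Named character vector of `n_genes` sequences, ids `t0001`, ...
#' @export
generate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 11L)
  n <- config$n_genes
  len <- config$transcript_length
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  setNames(seqs, sprintf("t%04d", seq_len(n)))
}

#' Generate paired-end tags with provenance
#'
#' Non-decoy pairs are extracted from a true transcript position with mates
#' in convergent orientation (forward mate upstream, reverse-complemented
#' mate downstream) and an outermost separation of at most `max_sep` nt, then
#' corrupted by per-base substitutions at `mismatch_rate` and N masking at
#' `n_rate`. Decoys are random sequences with no source. A pair whose total
#' N count exceeds 5 is labelled `expected_filtered`, matching the tag
#' admission rule applied downstream.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param n_pairs_per_transcript Pairs drawn from each transcript.
#' @param mismatch_rate,n_rate Per-base corruption probabilities in `[0, 1]`.
#' @param decoy_fraction Fraction of emitted pairs that are decoys.
#' @param seed Integer seed.
#' @param tag_length Tag length (nt).
#' @param max_sep Maximal outermost separation (nt) used when drawing pairs.
#' @return data.frame with columns pair_id, tag1, tag2, source_transcript,
#'   pos1, pos2 (0-based starts), separation, n_count, expected_filtered,
#'   is_decoy.
#' @export
generate_tag_pairs <- function(transcripts, n_pairs_per_transcript = 4L,
                               mismatch_rate = 0, n_rate = 0,
                               decoy_fraction = 0, seed = 1L,
                               tag_length = 20L, max_sep = 500L) {
  stopifnot(length(transcripts) >= 1L, !is.null(names(transcripts)))
  rates <- c(mismatch_rate, n_rate, decoy_fraction)
  if (any(rates < 0) || any(rates > 1)) {
    stop("invalid config: rates must lie in [0, 1]")
  }
  set.seed(seed)
  tl <- as.integer(tag_length)

  corrupt <- function(tag) {
    chars <- strsplit(tag, "", fixed = TRUE)[[1]]
    if (mismatch_rate > 0) {
      hit <- runif(length(chars)) < mismatch_rate
      for (i in which(hit)) {
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
      }
    }
    if (n_rate > 0) {
      chars[runif(length(chars)) < n_rate] <- "N"
    }
    paste(chars, collapse = "")
  }

  rows <- list()
  for (tx in names(transcripts)) {
    s <- transcripts[[tx]]
    len <- nchar(s)
    if (len < 2L * tl) stop("transcript ", tx, " shorter than two tags")
    for (k in seq_len(n_pairs_per_transcript)) {
      span <- sample(seq(2L * tl, min(max_sep, len)), 1L)
      start1 <- sample(seq(0L, len - span), 1L)           # 0-based
      pos2 <- start1 + span - tl
      tag1 <- substr(s, start1 + 1L, start1 + tl)
      tag2 <- rev_comp(substr(s, pos2 + 1L, pos2 + tl))
      rows[[length(rows) + 1L]] <- data.frame(
        tag1 = corrupt(tag1), tag2 = corrupt(tag2),
        source_transcript = tx, pos1 = start1, pos2 = pos2,
        separation = span, is_decoy = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)

  if (decoy_fraction > 0) {
    n_real <- nrow(df)
    n_decoy <- round(n_real * decoy_fraction / (1 - decoy_fraction))
    if (n_decoy > 0L) {
      decoys <- data.frame(
        tag1 = vapply(seq_len(n_decoy), function(i)
          paste(sample(c("A", "C", "G", "T"), tl, TRUE), collapse = ""),
          character(1)),
        tag2 = vapply(seq_len(n_decoy), function(i)
          paste(sample(c("A", "C", "G", "T"), tl, TRUE), collapse = ""),
          character(1)),
        source_transcript = NA_character_, pos1 = NA_integer_,
        pos2 = NA_integer_, separation = NA_integer_, is_decoy = TRUE,
        stringsAsFactors = FALSE)
      df <- rbind(df, decoys)
    }
  }

  df$pair_id <- sprintf("p%05d", seq_len(nrow(df)))
  n1 <- vapply(strsplit(df$tag1, "", fixed = TRUE),
               function(x) sum(x == "N"), integer(1))
  n2 <- vapply(strsplit(df$tag2, "", fixed = TRUE),
               function(x) sum(x == "N"), integer(1))
  df$n_count <- n1 + n2
  df$expected_filtered <- df$n_count > 5L
  df[, c("pair_id", "tag1", "tag2", "source_transcript", "pos1", "pos2",
         "separation", "n_count", "expected_filtered", "is_decoy")]
}
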