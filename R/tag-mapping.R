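# Paired-end tag mapping at toy scale: N-content admission, ungapped
# matching with at most one mismatch per tag (N is a wildcard on either
# side), convergent-orientation pairing, a 500 nt outermost-separation cap
# and the unique-mRNA rule. Coordinates are 0-based half-open throughout.

#' N-content admission filter for a tag pair
#'
#' A pair is admitted when the total number of N characters across both
#' mates is at most 5.
#'
#' @param tag1,tag2 Nucleotide strings over A/C/G/T/N.
#' @return TRUE if the pair passes.
#' @export
pair_n_filter <- function(tag1, tag2) {
  stopifnot(nzchar(tag1), nzchar(tag2))
  n_of <- function(x) sum(strsplit(x, "", fixed = TRUE)[[1]] == "N")
  n_of(tag1) + n_of(tag2) <= 5L
}

# column-major (k x n_off) index matrix mapping window positions into a
# sequence of length L; reused across scans of equal geometry
scan_index <- function(k, L) {
  n_off <- L - k + 1L
  rep(seq_len(n_off), each = k) + rep(seq_len(k) - 1L, n_off)
}

# mismatch counts of `tag_chars` against every offset of `seq_chars`;
# N on either side matches anything at no cost. Returns list(pos (0-based),
# mm) restricted to offsets within the budget.
mismatch_scan <- function(tag_chars, seq_chars, max_mismatch, idx = NULL) {
  k <- length(tag_chars)
  L <- length(seq_chars)
  if (k > L) return(list(pos = integer(0), mm = integer(0)))
  n_off <- L - k + 1L
  if (is.null(idx)) idx <- scan_index(k, L)
  s <- seq_chars[idx]
  d <- s != tag_chars                      # tag recycles per column
  if (any(seq_chars == N_BYTE)) d <- d & s != N_BYTE
  if (any(tag_chars == N_BYTE)) d <- d & tag_chars != N_BYTE
  dim(d) <- c(k, n_off)
  mm <- colSums(d)
  keep <- which(mm <= max_mismatch)
  list(pos = keep - 1L, mm = as.integer(mm[keep]))
}

# sequences are scanned as raw bytes; accepts a string, a pre-split
# character vector, or an already-converted raw vector
as_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (length(x) > 1L) x <- paste(x, collapse = "")
  charToRaw(x)
}

N_BYTE <- charToRaw("N")

#' Ungapped tag matching against one transcript
#'
#' Reports every position (both orientations: the tag as given on the plus
#' strand and its reverse complement on the minus strand) where the tag
#' aligns without gaps with at most `max_mismatch` mismatches. N in the tag
#' or the transcript matches any base at no mismatch cost. A tag longer
#' than the transcript yields an empty result.
#'
#' @param tag Nucleotide string.
#' @param transcript Transcript sequence (character string), or a
#'   pre-split character vector of single bases.
#' @param max_mismatch Mismatch budget per tag (default 1).
#' @return data.frame(pos (0-based start), strand ("+"/"-"), mismatches).
#' @export
match_tag <- function(tag, transcript, max_mismatch = 1L) {
  seq_chars <- as_bytes(transcript)
  fwd <- mismatch_scan(as_bytes(tag), seq_chars, max_mismatch)
  rev <- mismatch_scan(as_bytes(rev_comp(tag)), seq_chars, max_mismatch)
  data.frame(pos = c(fwd$pos, rev$pos),
             strand = rep(c("+", "-"), c(length(fwd$pos), length(rev$pos))),
             mismatches = c(fwd$mm, rev$mm), stringsAsFactors = FALSE)
}

# all convergent placements given forward/reverse scans of both mates:
# the plus-strand mate must start at or left of the minus-strand mate;
# separation is the outermost span. Returns list(pos1, pos2, strand1, mm1,
# mm2, sep) over both mate orientations.
convergent_placements <- function(f1, r1, f2, r2, len1, len2) {
  pos1 <- integer(0); pos2 <- integer(0); strand1 <- character(0)
  mm1 <- integer(0); mm2 <- integer(0); sep <- integer(0)
  # tag1 forward (upstream), tag2 reverse (downstream)
  if (length(f1$pos) && length(r2$pos)) {
    g <- expand.grid(i = seq_along(f1$pos), j = seq_along(r2$pos))
    ok <- f1$pos[g$i] <= r2$pos[g$j]
    if (any(ok)) {
      i <- g$i[ok]; j <- g$j[ok]
      pos1 <- c(pos1, f1$pos[i]); pos2 <- c(pos2, r2$pos[j])
      strand1 <- c(strand1, rep("+", sum(ok)))
      mm1 <- c(mm1, f1$mm[i]); mm2 <- c(mm2, r2$mm[j])
      sep <- c(sep, r2$pos[j] + len2 - f1$pos[i])
    }
  }
  # tag2 forward (upstream), tag1 reverse (downstream)
  if (length(f2$pos) && length(r1$pos)) {
    g <- expand.grid(i = seq_along(r1$pos), j = seq_along(f2$pos))
    ok <- f2$pos[g$j] <= r1$pos[g$i]
    if (any(ok)) {
      i <- g$i[ok]; j <- g$j[ok]
      pos1 <- c(pos1, r1$pos[i]); pos2 <- c(pos2, f2$pos[j])
      strand1 <- c(strand1, rep("-", sum(ok)))
      mm1 <- c(mm1, r1$mm[i]); mm2 <- c(mm2, f2$mm[j])
      sep <- c(sep, r1$pos[i] + len1 - f2$pos[j])
    }
  }
  if (!length(pos1)) return(NULL)
  list(pos1 = pos1, pos2 = pos2, strand1 = strand1, mm1 = mm1, mm2 = mm2,
       sep = sep)
}

#' Map one tag pair onto a transcript set
#'
#' A pair yields a valid hit iff (a) it passes [pair_n_filter()], (b) both
#' mates hit the same transcript in convergent orientation with at most
#' `max_mismatch` mismatches each, (c) the outermost separation (rightmost
#' end minus leftmost start) is at most `max_sep` nt, and (d) exactly one
#' transcript satisfies (b)+(c). Multiple placements on that single
#' transcript are resolved to the fewest total mismatches (ties: leftmost
#' mate-1 position, then leftmost mate-2 position); placements on two or
#' more transcripts reject the pair as `multi_mrna`.
#'
#' @param tag1,tag2 Mate sequences.
#' @param transcripts Named character vector of transcript sequences (or the
#'   pre-split list produced by [split_transcripts()]).
#' @param max_sep Maximal outermost separation in nt (default 500).
#' @param max_mismatch Mismatch budget per mate (default 1).
#' @param pair_id Identifier carried into the result.
#' @return list(status = "valid" or the rejection reason in
#'   {"n_filter", "no_hit", "multi_mrna", "too_far"}, hit = one-row
#'   data.frame or NULL).
#' @export
map_pair <- function(tag1, tag2, transcripts, max_sep = 500L,
                     max_mismatch = 1L, pair_id = NA_character_) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  if (!pair_n_filter(tag1, tag2)) {
    return(list(status = "n_filter", hit = NULL))
  }
  len1 <- nchar(tag1)
  len2 <- nchar(tag2)
  t1 <- as_bytes(tag1)
  t1rc <- as_bytes(rev_comp(tag1))
  t2 <- as_bytes(tag2)
  t2rc <- as_bytes(rev_comp(tag2))
  any_convergent <- FALSE
  hit_tx <- character(0)
  best <- NULL
  idx_cache <- list()
  for (tx in names(transcripts)) {
    seq_chars <- as_bytes(transcripts[[tx]])
    L <- length(seq_chars)
    key1 <- paste0(len1, ".", L)
    key2 <- paste0(len2, ".", L)
    if (is.null(idx_cache[[key1]]) && len1 <= L) {
      idx_cache[[key1]] <- scan_index(len1, L)
    }
    if (is.null(idx_cache[[key2]]) && len2 <= L) {
      idx_cache[[key2]] <- scan_index(len2, L)
    }
    f1 <- mismatch_scan(t1, seq_chars, max_mismatch, idx_cache[[key1]])
    f2 <- mismatch_scan(t2, seq_chars, max_mismatch, idx_cache[[key2]])
    r1 <- mismatch_scan(t1rc, seq_chars, max_mismatch, idx_cache[[key1]])
    r2 <- mismatch_scan(t2rc, seq_chars, max_mismatch, idx_cache[[key2]])
    pl <- convergent_placements(f1, r1, f2, r2, len1, len2)
    if (is.null(pl)) next
    any_convergent <- TRUE
    within <- pl$sep <= max_sep
    if (!any(within)) next
    hit_tx <- c(hit_tx, tx)
    if (length(hit_tx) > 1L) return(list(status = "multi_mrna", hit = NULL))
    ord <- order(pl$mm1[within] + pl$mm2[within], pl$pos1[within],
                 pl$pos2[within])[1]
    idx <- which(within)[ord]
    best <- list(tx = tx, pos1 = pl$pos1[idx], pos2 = pl$pos2[idx],
                 strand1 = pl$strand1[idx], mm1 = pl$mm1[idx],
                 mm2 = pl$mm2[idx], sep = pl$sep[idx])
  }
  if (is.null(best)) {
    return(list(status = if (any_convergent) "too_far" else "no_hit",
                hit = NULL))
  }
  hit <- data.frame(pair_id = pair_id, transcript_id = best$tx,
                    pos1 = best$pos1, pos2 = best$pos2,
                    strand1 = best$strand1,
                    strand2 = if (best$strand1 == "+") "-" else "+",
                    separation = best$sep,
                    mismatches1 = best$mm1, mismatches2 = best$mm2,
                    stringsAsFactors = FALSE)
  list(status = "valid", hit = hit)
}

#' Pre-convert transcripts to scannable byte vectors
#'
#' Avoids re-converting each transcript for every pair in [map_pairs()].
#'
#' @param transcripts Named character vector.
#' @return Named list of raw byte vectors.
#' @export
split_transcripts <- function(transcripts) {
  setNames(lapply(unname(transcripts), charToRaw), names(transcripts))
}

#' Map a table of tag pairs
#'
#' @param pairs data.frame with columns pair_id, tag1, tag2.
#' @param transcripts Named character vector of transcript sequences.
#' @param max_sep,max_mismatch Filters as in [map_pair()].
#' @return list(hits = data.frame of valid [map_pair()] hits,
#'   rejections = data.frame(pair_id, reason)).
#' @export
map_pairs <- function(pairs, transcripts, max_sep = 500L, max_mismatch = 1L) {
  stopifnot(all(c("pair_id", "tag1", "tag2") %in% names(pairs)))
  if (length(transcripts) == 0L) stop("empty transcript set")
  pre <- if (is.list(transcripts)) transcripts else split_transcripts(transcripts)
  hits <- vector("list", nrow(pairs))
  reasons <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- map_pair(pairs$tag1[i], pairs$tag2[i], pre,
                    max_sep = max_sep, max_mismatch = max_mismatch,
                    pair_id = pairs$pair_id[i])
    if (res$status == "valid") {
      hits[[i]] <- res$hit
    } else {
      reasons[i] <- res$status
    }
  }
  keep <- !vapply(hits, is.null, logical(1))
  empty_hits <- data.frame(pair_id = character(0), transcript_id = character(0),
                           pos1 = integer(0), pos2 = integer(0),
                           strand1 = character(0), strand2 = character(0),
                           separation = integer(0), mismatches1 = integer(0),
                           mismatches2 = integer(0), stringsAsFactors = FALSE)
  rej <- reasons != ""
  list(hits = if (any(keep)) do.call(rbind, hits[keep]) else empty_hits,
       rejections = data.frame(pair_id = pairs$pair_id[rej],
                               reason = reasons[rej],
                               stringsAsFactors = FALSE))
}

#' Count valid tag pairs per transcript
#'
#' Each valid pair is counted once for the transcript it maps to;
#' transcripts without hits get zero.
#'
#' @param hits data.frame of valid hits (needs `transcript_id`).
#' @param transcripts Named character vector (defines the count universe).
#' @return Named integer vector over all transcripts.
#' @export
count_tags <- function(hits, transcripts) {
  ids <- names(transcripts)
  unknown <- setdiff(unique(hits$transcript_id), ids)
  if (length(unknown)) {
    stop("hits reference unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  }
  counts <- setNames(integer(length(ids)), ids)
  if (nrow(hits)) {
    tab <- table(hits$transcript_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
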