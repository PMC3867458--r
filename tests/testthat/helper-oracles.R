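# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, enumeration, closed forms) and
# share no code with the implementation paths they check.

# a small, fast simulation configuration with no injected effects
small_config <- function(seed = 1L, n_genes = 20L, ...) {
  sim_config(seed = seed, n_genes = n_genes, n_affected_down = 0L,
             n_affected_up = 0L, ...)
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

# brute-force ungapped scan over all offsets and both strands
oracle_match_tag <- function(tag, transcript, max_mismatch = 1L) {
  trc <- strsplit(transcript, "", fixed = TRUE)[[1]]
  k <- nchar(tag)
  out <- data.frame(pos = integer(0), strand = character(0),
                    mismatches = integer(0), stringsAsFactors = FALSE)
  if (k > length(trc)) return(out)
  for (strand in c("+", "-")) {
    q <- strsplit(if (strand == "+") tag else revcomp_chr(tag),
                  "", fixed = TRUE)[[1]]
    for (p in 0:(length(trc) - k)) {
      w <- trc[(p + 1):(p + k)]
      mm <- sum(w != q & w != "N" & q != "N")
      if (mm <= max_mismatch) {
        out <- rbind(out, data.frame(pos = p, strand = strand,
                                     mismatches = mm,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# brute-force paired mapping applying the admission, convergence,
# separation and uniqueness rules independently of map_pair()
oracle_map_pair <- function(tag1, tag2, transcripts, max_sep = 500L,
                            max_mismatch = 1L) {
  n_total <- sum(strsplit(paste0(tag1, tag2), "", fixed = TRUE)[[1]] == "N")
  if (n_total > 5L) return(list(status = "n_filter"))
  len1 <- nchar(tag1)
  len2 <- nchar(tag2)
  any_b <- FALSE
  tx_hits <- list()
  for (tx in names(transcripts)) {
    h1 <- oracle_match_tag(tag1, transcripts[[tx]], max_mismatch)
    h2 <- oracle_match_tag(tag2, transcripts[[tx]], max_mismatch)
    placements <- NULL
    if (nrow(h1) && nrow(h2)) {
      for (i in seq_len(nrow(h1))) {
        for (j in seq_len(nrow(h2))) {
          if (h1$strand[i] == h2$strand[j]) next
          plus_pos <- if (h1$strand[i] == "+") h1$pos[i] else h2$pos[j]
          minus_pos <- if (h1$strand[i] == "-") h1$pos[i] else h2$pos[j]
          minus_len <- if (h1$strand[i] == "-") len1 else len2
          if (plus_pos > minus_pos) next
          any_b <- TRUE
          span <- minus_pos + minus_len - plus_pos
          if (span > max_sep) next
          placements <- rbind(placements, data.frame(
            pos1 = h1$pos[i], pos2 = h2$pos[j], strand1 = h1$strand[i],
            mm = h1$mismatches[i] + h2$mismatches[j],
            mm1 = h1$mismatches[i], mm2 = h2$mismatches[j],
            separation = span))
        }
      }
    }
    if (!is.null(placements)) tx_hits[[tx]] <- placements
  }
  if (length(tx_hits) == 0L) {
    return(list(status = if (any_b) "too_far" else "no_hit"))
  }
  if (length(tx_hits) > 1L) return(list(status = "multi_mrna"))
  pl <- tx_hits[[1]]
  pl <- pl[order(pl$mm, pl$pos1, pl$pos2), ]
  list(status = "valid", transcript_id = names(tx_hits), pos1 = pl$pos1[1],
       pos2 = pl$pos2[1], strand1 = pl$strand1[1],
       separation = pl$separation[1], mm1 = pl$mm1[1], mm2 = pl$mm2[1])
}

# Fisher exact test by full enumeration with log-factorial point
# probabilities (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(lp)
  p_obs <- probs[ks == a]
  list(p_two_sided = min(1, sum(probs[probs <= p_obs + 1e-12])),
       p_one_sided_greater = min(1, sum(probs[ks >= a])))
}

# sort-based linear-interpolation order statistic
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# random sequence helpers
rand_seq <- function(n, n_prob = 0) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, n, replace = TRUE)
  if (n_prob > 0) s[runif(n) < n_prob] <- "N"
  paste(s, collapse = "")
}
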