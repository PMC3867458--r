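# Chromatin-class assignment from cross-species ortholog mark states and
# contingency-based enrichment testing. The K27 class contains every gene
# marked by H3K27me3 regardless of H3K4me3 co-occupancy; K4-only genes
# carry H3K4me3 without H3K27me3.

#' Classify a gene from its mark flags
#'
#' @param k4,k27 Logical flags (vectorized) for H3K4me3 and H3K27me3.
#' @return Character vector over {"K27", "K4_only", "unmarked"}.
#' @export
classify_gene <- function(k4, k27) {
  stopifnot(length(k4) == length(k27))
  ifelse(k27, "K27", ifelse(k4, "K4_only", "unmarked"))
}

#' Per-species and conserved chromatin classes for every gene
#'
#' A gene's class is conserved iff both species are present and classify
#' identically to K27 or K4-only. The combined class takes the conserved
#' class when available; otherwise it is K27 if any species reports K27,
#' else K4-only if any species reports H3K4me3, else unmarked (mouse
#' and/or zebrafish evidence).
#'
#' @param states data.frame(gene_id, species, k4, k27), at most one row per
#'   (gene, species).
#' @return data.frame(gene_id, one class column per species, conserved,
#'   class).
#' @export
conserved_classes <- function(states) {
  stopifnot(all(c("gene_id", "species", "k4", "k27") %in% names(states)))
  if (anyDuplicated(states[, c("gene_id", "species")])) {
    stop("more than one row per (gene, species)")
  }
  states$class <- classify_gene(states$k4, states$k27)
  species <- sort(unique(states$species))
  genes <- unique(states$gene_id)
  cls <- matrix(NA_character_, length(genes), length(species),
                dimnames = list(genes, species))
  idx <- cbind(match(states$gene_id, genes), match(states$species, species))
  cls[idx] <- states$class
  agree <- if (length(species) == 2L) {
    both <- rowSums(!is.na(cls)) == 2L
    both & cls[, 1] == cls[, 2] & cls[, 1] %in% c("K27", "K4_only")
  } else rep(FALSE, length(genes))
  agree[is.na(agree)] <- FALSE
  combined <- apply(cls, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    if (any(x == "K27")) "K27"
    else if (any(x == "K4_only")) "K4_only"
    else "unmarked"
  })
  out <- data.frame(gene_id = genes, cls, conserved = unname(agree),
                    class = unname(combined), stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[2:(1 + length(species))] <- paste0("class_", species)
  rownames(out) <- NULL
  out
}

#' Conserved class of a single gene
#'
#' @param states EpiState table as in [conserved_classes()].
#' @param gene Gene id.
#' @return list(gene_id, per-species classes, conserved, class).
#' @export
conserved_class <- function(states, gene) {
  cc <- conserved_classes(states[states$gene_id == gene, , drop = FALSE])
  if (!nrow(cc)) {
    return(list(gene_id = gene, conserved = FALSE, class = NA_character_))
  }
  as.list(cc[1, ])
}

#' Build the 2x2 contingency table of mark positivity by gene set
#'
#' Rows: promoted / control membership; columns: mark positive / negative.
#'
#' @param promoted_genes,control_genes Disjoint gene-id vectors.
#' @param mark_calls data.frame(gene_id, positive); every gene in either
#'   set must have a call.
#' @return Named integer vector c(a, b, c, d): promoted-positive,
#'   promoted-negative, control-positive, control-negative.
#' @export
build_contingency <- function(promoted_genes, control_genes, mark_calls) {
  overlap <- intersect(promoted_genes, control_genes)
  if (length(overlap)) {
    stop("gene(s) in both sets: ", paste(overlap, collapse = ", "))
  }
  stopifnot(all(c("gene_id", "positive") %in% names(mark_calls)))
  missing <- setdiff(c(promoted_genes, control_genes), mark_calls$gene_id)
  if (length(missing)) {
    stop("gene(s) without a mark call: ", paste(missing, collapse = ", "))
  }
  pos <- mark_calls$gene_id[mark_calls$positive]
  a <- sum(promoted_genes %in% pos)
  c_ <- sum(control_genes %in% pos)
  c(a = a, b = length(promoted_genes) - a,
    c = c_, d = length(control_genes) - c_)
}

#' Fisher exact test on a 2x2 table (internal implementation)
#'
#' Exact conditional test from the hypergeometric family. The two-sided p
#' is the sum of probabilities of all tables with the same margins whose
#' point probability does not exceed that of the observed table (within
#' 1e-12); the one-sided "greater" p is the upper tail on the `a` cell.
#' The odds ratio is the sample value `ad/bc` (`Inf` when `bc = 0`).
#' A degenerate margin yields p = 1 with a flag.
#'
#' @param a,b,c,d Non-negative integer cells (row 1: a, b; row 2: c, d), or
#'   a 2x2 matrix as `a`.
#' @return list of class `fisher_result`: `p_two_sided`,
#'   `p_one_sided_greater`, `odds_ratio`, `table`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) < 1) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  odds <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  res <- list(table = matrix(cells, 2, 2, byrow = TRUE,
                             dimnames = list(c("promoted", "control"),
                                             c("positive", "negative"))),
              odds_ratio = odds)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    res$p_two_sided <- 1
    res$p_one_sided_greater <- 1
    res$degenerate <- TRUE
    class(res) <- "fisher_result"
    return(res)
  }
  k <- max(0L, c1 - r2):min(r1, c1)      # support of the a cell
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  res$p_two_sided <- min(1, sum(probs[probs <= p_obs + 1e-12]))
  res$p_one_sided_greater <- min(1, sum(probs[k >= a]))
  res$degenerate <- FALSE
  class(res) <- "fisher_result"
  res
}

#' @export
print.fisher_result <- function(x, ...) {
  print(x$table)
  cat("odds ratio:", format(x$odds_ratio, digits = 4),
      "; two-sided p:", format(x$p_two_sided, digits = 4),
      "; one-sided (greater) p:", format(x$p_one_sided_greater, digits = 4),
      "\n")
  if (x$degenerate) cat("(degenerate margin: p = 1 by convention)\n")
  invisible(x)
}

#' Three-way overlap summary
#'
#' Region counts of the partition generated by three gene sets (e.g.
#' PPARbeta-promoted, chromatin class, gastrula burst).
#'
#' @param set_a,set_b,set_c Character vectors of gene ids.
#' @param labels Names of the three sets.
#' @return Named integer vector of the 7 region counts plus set totals.
#' @export
overlap_summary <- function(set_a, set_b, set_c,
                            labels = c("A", "B", "C")) {
  a <- unique(set_a); b <- unique(set_b); c_ <- unique(set_c)
  universe <- union(union(a, b), c_)
  in_a <- universe %in% a
  in_b <- universe %in% b
  in_c <- universe %in% c_
  n <- function(sel) sum(sel)
  out <- c(
    n(in_a & !in_b & !in_c), n(!in_a & in_b & !in_c),
    n(!in_a & !in_b & in_c), n(in_a & in_b & !in_c),
    n(in_a & !in_b & in_c), n(!in_a & in_b & in_c),
    n(in_a & in_b & in_c), length(a), length(b), length(c_))
  names(out) <- c(
    paste0(labels[1], "_only"), paste0(labels[2], "_only"),
    paste0(labels[3], "_only"),
    paste0(labels[1], "_", labels[2]), paste0(labels[1], "_", labels[3]),
    paste0(labels[2], "_", labels[3]),
    paste(labels, collapse = "_"),
    paste0("total_", labels))
  out
}
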