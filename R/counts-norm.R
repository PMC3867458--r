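# Count normalization by distribution matching, under the assumption that
# most genes are unaffected by the knock-down: the MO column is rescaled so
# that its median matches the control median, folds are computed with a
# pseudocount, and the promoted/control candidate gene sets are built from
# the downregulation ranking.

#' Median-matching scale factor for the MO column
#'
#' Over genes detected in at least one condition (Co + MO > 0), returns
#' `median(Co) / median(MO)`; multiplying MO by the result equalizes the
#' medians of the two count distributions.
#'
#' @param table data.frame with columns `gene_id`, `Co`, `MO`.
#' @return Positive scalar.
#' @export
distribution_scale_factor <- function(table) {
  stopifnot(all(c("gene_id", "Co", "MO") %in% names(table)))
  if (any(table$Co < 0) || any(table$MO < 0)) stop("negative counts")
  keep <- (table$Co + table$MO) > 0
  if (!any(table$Co > 0) || !any(table$MO > 0)) {
    stop("degenerate input: a condition column is all zero")
  }
  m_co <- median(table$Co[keep])
  m_mo <- median(table$MO[keep])
  if (m_co <= 0 || m_mo <= 0) {
    stop("degenerate input: zero median among detected genes")
  }
  m_co / m_mo
}

#' Apply a scale factor to the MO column
#'
#' @param table data.frame with columns `gene_id`, `Co`, `MO`.
#' @param factor Positive scale factor (e.g. the output of
#'   [distribution_scale_factor()], or a published value supplied directly).
#' @return list of class `normalization_result`: `scale_factor`,
#'   `table` (MO adjusted, Co untouched), `summary` (five-number summaries
#'   of raw Co and adjusted MO).
#' @export
apply_scale <- function(table, factor) {
  stopifnot(all(c("gene_id", "Co", "MO") %in% names(table)))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("scale factor must be a positive scalar")
  }
  adj <- table
  adj$MO <- table$MO * factor
  summ <- rbind(Co = count_summary(adj$Co), MO = count_summary(adj$MO))
  res <- list(scale_factor = factor, table = adj, summary = summ)
  class(res) <- "normalization_result"
  res
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("normalization: MO column multiplied by",
      format(x$scale_factor, digits = 4), "\n")
  print(round(x$summary, 1))
  invisible(x)
}

#' Five-number summary of a count column
#'
#' Lowest, first quartile, median, third quartile and maximum, with
#' linear-interpolation quartiles.
#'
#' @param column Non-empty numeric vector.
#' @return Named numeric vector (lowest, q1, median, q3, maximum).
#' @export
count_summary <- function(column) {
  if (length(column) == 0L) stop("empty column")
  q <- quantile(column, probs = c(0, 0.25, 0.5, 0.75, 1),
                type = 7, names = FALSE)
  setNames(q, c("lowest", "q1", "median", "q3", "maximum"))
}

#' Per-gene relative abundance (MO/Co fold) and downregulation ranking
#'
#' fold = (adjusted MO + pseudocount) / (Co + pseudocount). Rank 1 is the
#' most downregulated gene; ties are broken by higher Co count, then by
#' gene id.
#'
#' @param norm A `normalization_result` from [apply_scale()].
#' @param pseudocount Positive pseudocount (default 0.5).
#' @return data.frame(gene_id, Co, MO_adj, fold, rank).
#' @export
relative_abundance <- function(norm, pseudocount = 0.5) {
  stopifnot(inherits(norm, "normalization_result"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  tab <- norm$table
  fold <- (tab$MO + pseudocount) / (tab$Co + pseudocount)
  ord <- order(fold, -tab$Co, tab$gene_id)
  rank <- integer(length(fold))
  rank[ord] <- seq_along(ord)
  data.frame(gene_id = tab$gene_id, Co = tab$Co, MO_adj = tab$MO,
             fold = fold, rank = rank, stringsAsFactors = FALSE)
}

#' Build promoted-candidate and unchanged-control gene sets
#'
#' Promoted candidates are the `top_n` most downregulated genes (the MO
#' lowers their transcripts, so PPARbeta promotes them); control candidates
#' are genes whose fold lies inside `unchanged_band`, excluding any gene
#' already in the promoted set.
#'
#' @param reg A [relative_abundance()] table.
#' @param top_n Size of the promoted-candidate set (default 200).
#' @param unchanged_band Length-2 numeric interval that must contain 1.
#' @return list(promoted_candidates, control_candidates) of gene ids.
#' @export
select_gene_sets <- function(reg, top_n = 200L,
                             unchanged_band = c(0.9, 1.1)) {
  stopifnot(all(c("gene_id", "fold", "rank") %in% names(reg)))
  if (top_n > nrow(reg)) stop("top_n exceeds the number of genes")
  if (length(unchanged_band) != 2L || unchanged_band[1] > 1 ||
      unchanged_band[2] < 1) {
    stop("invalid config: unchanged_band must contain 1")
  }
  promoted <- reg$gene_id[reg$rank <= top_n]
  in_band <- reg$fold >= unchanged_band[1] & reg$fold <= unchanged_band[2]
  control <- setdiff(reg$gene_id[in_band], promoted)
  list(promoted_candidates = promoted, control_candidates = control)
}
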