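# Developmental dynamics: transcriptome change rates across stage
# transitions (fold thresholds 2/4/8, counts normalized by transition
# duration in hours) and persistence profiles of gastrula-induced genes.

#' Construct an expression time course
#'
#' @param levels Positive numeric matrix, genes x stages, with dimnames.
#' @param durations_h Hours between consecutive stages
#'   (length = ncol(levels) - 1).
#' @return list of class `expression_timecourse`: `levels`, `stages`,
#'   `durations_h`.
#' @export
expression_timecourse <- function(levels, durations_h) {
  stopifnot(is.matrix(levels), !is.null(rownames(levels)),
            !is.null(colnames(levels)))
  if (length(durations_h) != ncol(levels) - 1L) {
    stop("durations_h must have ncol(levels) - 1 entries")
  }
  if (any(durations_h <= 0)) stop("durations must be positive")
  if (any(levels < 0)) stop("levels must be non-negative")
  tc <- list(levels = levels, stages = colnames(levels),
             durations_h = as.numeric(durations_h))
  class(tc) <- "expression_timecourse"
  tc
}

#' @export
print.expression_timecourse <- function(x, ...) {
  cat("expression time course:", nrow(x$levels), "genes x",
      length(x$stages), "stages (", paste(x$stages, collapse = " > "), ")\n")
  invisible(x)
}

default_floor <- function(levels) {
  pos <- levels[levels > 0]
  if (!length(pos)) stop("all levels are zero")
  0.5 * min(pos)
}

#' Transition-rate table of fold-change counts
#'
#' For each consecutive stage pair, counts genes whose level increases or
#' decreases by at least each fold threshold,
#' `level(next) / max(level(prev), floor) >= t` (symmetrically for
#' decreases), and normalizes counts by the transition duration in hours.
#'
#' @param tc An [expression_timecourse()].
#' @param thresholds Fold thresholds > 1 (default 2, 4, 8).
#' @param floor Positive floor guarding folds against zero levels; default
#'   half the smallest positive level.
#' @return data.frame(transition, from, to, duration_h, threshold,
#'   direction, n_genes, rate_per_h).
#' @export
transition_rates <- function(tc, thresholds = c(2, 4, 8), floor = NULL) {
  stopifnot(inherits(tc, "expression_timecourse"))
  if (any(thresholds <= 1)) stop("thresholds must exceed 1")
  if (is.null(floor)) floor <- default_floor(tc$levels)
  if (floor <= 0) stop("floor must be positive")
  lv <- tc$levels
  rows <- list()
  for (s in seq_len(ncol(lv) - 1L)) {
    prev <- pmax(lv[, s], floor)
    nxt <- pmax(lv[, s + 1L], floor)
    fold <- nxt / prev
    dur <- tc$durations_h[s]
    for (t in thresholds) {
      for (dir in c("increase", "decrease")) {
        n <- if (dir == "increase") sum(fold >= t) else sum(fold <= 1 / t)
        rows[[length(rows) + 1L]] <- data.frame(
          transition = paste0(tc$stages[s], ">", tc$stages[s + 1L]),
          from = tc$stages[s], to = tc$stages[s + 1L], duration_h = dur,
          threshold = t, direction = dir, n_genes = n,
          rate_per_h = n / dur, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Genes bursting between two stages
#'
#' @param tc An [expression_timecourse()].
#' @param from_stage,to_stage Stage labels; `from_stage` must precede
#'   `to_stage`.
#' @param min_fold Minimal fold increase (default 4).
#' @param floor Zero guard as in [transition_rates()].
#' @return Character vector of gene ids with
#'   `level(to) / max(level(from), floor) >= min_fold`.
#' @export
burst_set <- function(tc, from_stage, to_stage, min_fold = 4, floor = NULL) {
  stopifnot(inherits(tc, "expression_timecourse"))
  i <- match(from_stage, tc$stages)
  j <- match(to_stage, tc$stages)
  if (is.na(i) || is.na(j)) stop("unknown stage label")
  if (i >= j) stop("from_stage must precede to_stage")
  if (is.null(floor)) floor <- default_floor(tc$levels)
  fold <- tc$levels[, j] / pmax(tc$levels[, i], floor)
  rownames(tc$levels)[fold >= min_fold]
}

#' Per-stage quantile envelope of a gene set
#'
#' The 10th, 25th, 50th, 75th and 90th percentiles of the expression levels
#' of `gene_set` at every stage (linear-interpolation quantiles); used to
#' check that gastrula-induced genes maintain their higher expression at
#' later stages.
#'
#' @param tc An [expression_timecourse()].
#' @param gene_set Non-empty vector of gene ids present in the course.
#' @return data.frame(stage, p10, p25, p50, p75, p90).
#' @export
persistence_profile <- function(tc, gene_set) {
  stopifnot(inherits(tc, "expression_timecourse"))
  if (!length(gene_set)) stop("empty gene set")
  missing <- setdiff(gene_set, rownames(tc$levels))
  if (length(missing)) {
    stop("gene(s) not in time course: ", paste(missing, collapse = ", "))
  }
  lv <- tc$levels[gene_set, , drop = FALSE]
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  q <- apply(lv, 2, quantile, probs = probs, type = 7, names = FALSE)
  out <- data.frame(stage = tc$stages, t(q), stringsAsFactors = FALSE)
  names(out) <- c("stage", "p10", "p25", "p50", "p75", "p90")
  rownames(out) <- NULL
  out
}
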