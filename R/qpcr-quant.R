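# qPCR quantification: threshold-cycle calling, window-of-linearity
# efficiency estimation from the log-linear phase of each amplification
# curve, efficiency-corrected relative quantities with a mean-Ct
# calibrator, geometric-mean reference-gene normalization and replicate
# MO/Co fold summaries.

#' Call the threshold cycle (Ct) of one amplification curve
#'
#' The baseline (mean fluorescence of the first three cycles) is
#' subtracted; Ct is the interpolated fractional cycle at which the
#' corrected fluorescence first reaches `threshold`. Interpolation between
#' the flanking cycles is done on the log-fluorescence scale (exact for an
#' exponentially growing signal), falling back to linear interpolation when
#' the lower flanking value is not positive.
#'
#' @param cycles Strictly increasing integer cycles (>= 10 points).
#' @param fluorescence Fluorescence readings, one per cycle.
#' @param threshold Detection threshold (above baseline, below the maximal
#'   corrected fluorescence).
#' @return Fractional cycle, or `NA_real_` (no-amplification flag) when the
#'   curve never crosses the threshold.
#' @export
call_ct <- function(cycles, fluorescence, threshold) {
  stopifnot(length(cycles) == length(fluorescence), length(cycles) >= 10L,
            all(diff(cycles) > 0), threshold > 0)
  corr <- fluorescence - mean(fluorescence[1:3])
  idx <- which(corr >= threshold)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(as.numeric(cycles[1]))
  f0 <- corr[i - 1L]
  f1 <- corr[i]
  frac <- if (f0 > 0) {
    (log(threshold) - log(f0)) / (log(f1) - log(f0))
  } else {
    (threshold - f0) / (f1 - f0)
  }
  cycles[i - 1L] + frac * (cycles[i] - cycles[i - 1L])
}

#' Call Cts for a long-format curve table
#'
#' @param curves data.frame(well_id, primer_id, sample_id, cycle,
#'   fluorescence).
#' @param threshold Detection threshold passed to [call_ct()].
#' @return data.frame(well_id, primer_id, sample_id, ct, no_amplification).
#' @export
call_cts <- function(curves, threshold) {
  stopifnot(all(c("well_id", "cycle", "fluorescence") %in% names(curves)))
  wells <- unique(curves$well_id)
  rows <- lapply(wells, function(w) {
    cc <- curves[curves$well_id == w, ]
    cc <- cc[order(cc$cycle), ]
    ct <- call_ct(cc$cycle, cc$fluorescence, threshold)
    data.frame(well_id = w,
               primer_id = if ("primer_id" %in% names(cc)) cc$primer_id[1] else NA,
               sample_id = if ("sample_id" %in% names(cc)) cc$sample_id[1] else NA,
               ct = ct, no_amplification = is.na(ct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# best sliding window (slope, r2, start) of y over x, windows of `window`
# consecutive points
best_linear_window <- function(x, y, window) {
  n <- length(x)
  best <- list(r2 = -Inf, slope = NA_real_, start = NA_real_)
  if (n < window) return(best)
  for (i in seq_len(n - window + 1L)) {
    xi <- x[i:(i + window - 1L)]
    yi <- y[i:(i + window - 1L)]
    if (any(diff(xi) != 1)) next           # window must be contiguous cycles
    xm <- xi - mean(xi)
    ym <- yi - mean(yi)
    sxx <- sum(xm^2)
    syy <- sum(ym^2)
    if (syy == 0) next
    slope <- sum(xm * ym) / sxx
    r2 <- (sum(xm * ym))^2 / (sxx * syy)
    if (r2 > best$r2) best <- list(r2 = r2, slope = slope, start = xi[1])
  }
  best
}

#' Estimate amplification efficiency for one primer (window of linearity)
#'
#' Per well: the baseline (mean of the first three cycles) is subtracted
#' and the corrected fluorescence is log10-transformed. When the curve
#' reaches a plateau, the transform additionally linearizes the saturating
#' amplification response against the observed plateau (mean corrected
#' fluorescence of the last three cycles), `log10(F) - log10(1 - F/plateau)`,
#' and points at 95% of the plateau or above are excluded; this keeps the
#' window of linearity unbiased by the onset of saturation. A contiguous
#' window of `window` cycles with maximal R-squared is then selected and the
#' well efficiency is `10^slope`. The primer efficiency is the arithmetic
#' mean over wells whose best window reaches `min_r2` with a positive
#' slope; the others are excluded and reported.
#'
#' @param curves Long-format curves of a single primer.
#' @param window Window length in cycles (default 5).
#' @param min_r2 Minimal R-squared for a well to contribute (default 0.99).
#' @return list of class `primer_efficiency`: `primer_id`, `efficiency`,
#'   `n_wells_used`, `fits` (per-well window fits), `excluded` (well ids).
#' @export
estimate_efficiency <- function(curves, window = 5L, min_r2 = 0.99) {
  stopifnot(all(c("well_id", "cycle", "fluorescence") %in% names(curves)))
  primer <- if ("primer_id" %in% names(curves)) unique(curves$primer_id)
            else NA_character_
  if (length(primer) > 1L) stop("curves span multiple primers: ",
                                paste(primer, collapse = ", "))
  wells <- unique(curves$well_id)
  fits <- lapply(wells, function(w) {
    cc <- curves[curves$well_id == w, ]
    cc <- cc[order(cc$cycle), ]
    corr <- cc$fluorescence - mean(cc$fluorescence[1:3])
    plateau <- mean(utils::tail(corr, 3))
    if (is.finite(plateau) && plateau > 0) {
      keep <- corr > 0 & corr < 0.95 * plateau
      y <- log10(corr[keep]) - log10(1 - corr[keep] / plateau)
    } else {
      keep <- corr > 0
      y <- log10(corr[keep])
    }
    if (sum(keep) < window) {        # plateau bound left too few points
      keep <- corr > 0
      y <- log10(corr[keep])
    }
    b <- best_linear_window(cc$cycle[keep], y, window)
    data.frame(well_id = w, start_cycle = b$start, slope = b$slope,
               r2 = b$r2, efficiency = 10^b$slope, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  ok <- is.finite(fits$r2) & fits$r2 >= min_r2 & fits$slope > 0
  if (!any(ok)) {
    stop("efficiency estimation failed for primer ", primer,
         ": no well reached R^2 >= ", min_r2)
  }
  res <- list(primer_id = primer, efficiency = mean(fits$efficiency[ok]),
              n_wells_used = sum(ok), fits = fits,
              excluded = fits$well_id[!ok])
  class(res) <- "primer_efficiency"
  res
}

#' @export
print.primer_efficiency <- function(x, ...) {
  cat("primer", x$primer_id, ": E =", format(x$efficiency, digits = 4),
      "from", x$n_wells_used, "well(s)\n")
  invisible(x)
}

#' Estimate efficiencies for every primer in a curve table
#'
#' @param curves Long-format curve table with a `primer_id` column.
#' @inheritParams estimate_efficiency
#' @return Named numeric vector, primer -> mean efficiency.
#' @export
estimate_efficiencies <- function(curves, window = 5L, min_r2 = 0.99) {
  primers <- unique(curves$primer_id)
  vapply(primers, function(pr) {
    estimate_efficiency(curves[curves$primer_id == pr, ],
                        window = window, min_r2 = min_r2)$efficiency
  }, numeric(1))
}

#' Efficiency-corrected relative quantities for one gene
#'
#' RQ_sample = E^(Ct_calibrator - Ct_sample), with the calibrator taken as
#' the arithmetic mean Ct across the gene's samples (so RQs are
#' mean-centred). Samples with missing Ct are skipped with a message.
#'
#' @param ct data.frame(sample_id, ct) for one gene (a `gene_id` column is
#'   carried through if present).
#' @param efficiency Amplification efficiency E > 1 (a scalar or a
#'   `primer_efficiency`).
#' @return data.frame(gene_id, sample_id, rq).
#' @export
relative_quantity <- function(ct, efficiency) {
  if (inherits(efficiency, "primer_efficiency")) {
    efficiency <- efficiency$efficiency
  }
  if (efficiency <= 1) stop("efficiency must be > 1")
  stopifnot(all(c("sample_id", "ct") %in% names(ct)))
  gene <- if ("gene_id" %in% names(ct)) ct$gene_id[1] else NA_character_
  miss <- is.na(ct$ct)
  if (any(miss)) {
    message("skipping ", sum(miss), " sample(s) with missing Ct for gene ",
            gene)
    ct <- ct[!miss, , drop = FALSE]
  }
  calib <- mean(ct$ct)
  data.frame(gene_id = gene, sample_id = ct$sample_id,
             rq = efficiency^(calib - ct$ct), stringsAsFactors = FALSE)
}

#' Relative quantities for a gene-by-sample Ct table
#'
#' @param ct_table data.frame(gene_id, sample_id, ct).
#' @param efficiencies Named vector, gene -> efficiency.
#' @return data.frame(gene_id, sample_id, rq).
#' @export
relative_quantities <- function(ct_table, efficiencies) {
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct_table)))
  genes <- unique(ct_table$gene_id)
  missing_e <- setdiff(genes, names(efficiencies))
  if (length(missing_e)) {
    stop("no efficiency for gene(s): ", paste(missing_e, collapse = ", "))
  }
  do.call(rbind, lapply(genes, function(g) {
    relative_quantity(ct_table[ct_table$gene_id == g, ], efficiencies[[g]])
  }))
}

#' Normalize relative quantities to reference genes
#'
#' Per sample, the normalization factor is the geometric mean of the
#' reference-gene RQs; every RQ in that sample is divided by it.
#'
#' @param rq data.frame(gene_id, sample_id, rq).
#' @param reference_genes Reference gene ids (default EEF1a and RPL8).
#' @return data.frame(gene_id, sample_id, rq, norm_factor, rq_norm).
#' @export
normalize_to_references <- function(rq,
                                    reference_genes = c("EEF1a", "RPL8")) {
  stopifnot(all(c("gene_id", "sample_id", "rq") %in% names(rq)))
  samples <- unique(rq$sample_id)
  nf <- vapply(samples, function(s) {
    ref <- rq[rq$sample_id == s & rq$gene_id %in% reference_genes, ]
    absent <- setdiff(reference_genes, ref$gene_id)
    if (length(absent)) {
      stop("sample ", s, " lacks reference gene(s): ",
           paste(absent, collapse = ", "))
    }
    exp(mean(log(ref$rq)))
  }, numeric(1))
  rq$norm_factor <- nf[match(rq$sample_id, samples)]
  rq$rq_norm <- rq$rq / rq$norm_factor
  rq
}

#' Per-gene MO/Co fold across replicates
#'
#' Per replicate, fold = normalized RQ(MO) / normalized RQ(Co); the mean
#' fold and the standard error of the mean across replicates are reported
#' (SEM is `NA` with a single replicate). Genes with a missing or zero Co
#' quantity in any replicate are flagged and excluded.
#'
#' @param normalized Output of [normalize_to_references()].
#' @param sample_info data.frame(sample_id, condition in {"Co","MO"},
#'   replicate).
#' @return data.frame(gene_id, mean_fold, sem, n_replicates), with excluded
#'   genes in `attr(, "excluded")`.
#' @export
fold_mo_vs_co <- function(normalized, sample_info) {
  stopifnot(all(c("gene_id", "sample_id", "rq_norm") %in% names(normalized)),
            all(c("sample_id", "condition", "replicate") %in% names(sample_info)))
  stopifnot(all(sample_info$condition %in% c("Co", "MO")))
  m <- merge(normalized, sample_info, by = "sample_id")
  genes <- unique(m$gene_id)
  excluded <- character(0)
  rows <- list()
  for (g in genes) {
    gm <- m[m$gene_id == g, ]
    reps <- unique(gm$replicate)
    folds <- rep(NA_real_, length(reps))
    ok <- TRUE
    for (k in seq_along(reps)) {
      co <- gm$rq_norm[gm$replicate == reps[k] & gm$condition == "Co"]
      mo <- gm$rq_norm[gm$replicate == reps[k] & gm$condition == "MO"]
      if (length(co) != 1L || length(mo) != 1L || !is.finite(co) || co <= 0) {
        ok <- FALSE
        break
      }
      folds[k] <- mo / co
    }
    if (!ok) {
      excluded <- c(excluded, g)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, mean_fold = mean(folds),
      sem = if (length(folds) > 1L) sd(folds) / sqrt(length(folds))
            else NA_real_,
      n_replicates = length(folds), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), mean_fold = numeric(0),
               sem = numeric(0), n_replicates = integer(0))
  attr(out, "excluded") <- excluded
  out
}
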