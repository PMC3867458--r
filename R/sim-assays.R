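# Assay-level generators: tag-count tables, qPCR amplification curves,
# ChIP Ct tables, developmental time courses and ortholog chromatin states.
# Every generator returns a list with the simulated data and a `truth`
# element; downstream analysis functions never read `truth` (tests do).

#' Generate a control/morpholino tag-count experiment
#'
#' Control (Co) counts are negative binomial around log-normal per-gene
#' means; MO counts use the same means multiplied by the injected fold (for
#' affected genes) and by the global `library_scale` (the normalization
#' ground truth). The majority of genes are unaffected.
#'
#' @param config A [sim_config()].
#' @return list(counts = data.frame(gene_id, Co, MO),
#'   truth = list(affected_genes = named fold vector, library_scale)).
#' @export
generate_count_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 21L)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  mu <- rlnorm(n, config$mean_log_expression, config$sd_log_expression)

  fold <- rep(1, n)
  n_dn <- config$n_affected_down
  n_up <- config$n_affected_up
  affected_idx <- if (n_dn + n_up > 0L) sample(n, n_dn + n_up) else integer(0)
  dn_idx <- head(affected_idx, n_dn)
  up_idx <- utils::tail(affected_idx, n_up)
  mag <- function(k) runif(k, config$effect_fold_range[1],
                           config$effect_fold_range[2])
  if (n_dn > 0L) fold[dn_idx] <- 1 / mag(n_dn)
  if (n_up > 0L) fold[up_idx] <- mag(n_up)

  size <- 1 / config$nb_dispersion
  co <- rnbinom(n, size = size, mu = mu)
  mo <- rnbinom(n, size = size, mu = mu * fold * config$library_scale)

  affected <- setNames(fold[affected_idx], genes[affected_idx])
  list(counts = data.frame(gene_id = genes, Co = co, MO = mo,
                           stringsAsFactors = FALSE),
       truth = list(affected_genes = affected,
                    down_genes = genes[dn_idx], up_genes = genes[up_idx],
                    library_scale = config$library_scale))
}

#' True crossing cycle of the saturating curve model
#'
#' Solves `F0 E^c / (1 + F0 E^c / fmax) = threshold` for the fractional
#' cycle c.
#'
#' @param f0 Initial signal.
#' @param efficiency Per-cycle amplification factor E.
#' @param fmax Plateau fluorescence.
#' @param threshold Detection threshold (same units as fluorescence).
#' @return Fractional cycle.
#' @export
true_crossing_cycle <- function(f0, efficiency, fmax, threshold) {
  stopifnot(threshold > 0, threshold < fmax)
  log(threshold / (f0 * (1 - threshold / fmax))) / log(efficiency)
}

#' Generate synthetic qPCR amplification curves
#'
#' Fluorescence follows `baseline + F0 E^c / (1 + F0 E^c / fmax)` plus
#' Gaussian noise. Each well's true efficiency, F0 and crossing cycle (at
#' threshold `curve_threshold_frac * fmax`) are recorded in the truth table.
#'
#' @param config A [sim_config()]; `true_efficiencies` names the primers.
#' @param n_wells_per_primer Wells per primer.
#' @param primers Primer subset (default all in config).
#' @param cycles Integer cycle grid.
#' @param crossing_cycles Optional numeric vector (recycled over wells of a
#'   primer) of true crossing cycles; default uniform in [18, 24].
#' @param sample_ids Optional sample labels (recycled over wells).
#' @return list(curves = long data.frame(well_id, primer_id, sample_id,
#'   cycle, fluorescence), truth = per-well data.frame).
#' @export
generate_amplification_curves <- function(config, n_wells_per_primer = 8L,
                                          primers = names(config$true_efficiencies),
                                          cycles = 1:40,
                                          crossing_cycles = NULL,
                                          sample_ids = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 31L)
  thr <- config$curve_threshold_frac * config$fmax
  curve_rows <- list()
  truth_rows <- list()
  for (pr in primers) {
    e <- config$true_efficiencies[[pr]]
    cross <- if (is.null(crossing_cycles)) {
      runif(n_wells_per_primer, 18, 24)
    } else rep_len(crossing_cycles, n_wells_per_primer)
    samp <- if (is.null(sample_ids)) rep(NA_character_, n_wells_per_primer)
            else rep_len(sample_ids, n_wells_per_primer)
    for (w in seq_len(n_wells_per_primer)) {
      f0 <- thr / (1 - thr / config$fmax) * e^(-cross[w])
      signal <- f0 * e^cycles / (1 + f0 * e^cycles / config$fmax)
      noise <- if (config$curve_noise_sd > 0) {
        rnorm(length(cycles), 0, config$curve_noise_sd * config$fmax)
      } else 0
      wid <- sprintf("%s_w%02d", pr, w)
      curve_rows[[length(curve_rows) + 1L]] <- data.frame(
        well_id = wid, primer_id = pr, sample_id = samp[w], cycle = cycles,
        fluorescence = config$curve_baseline + signal + noise,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        well_id = wid, primer_id = pr, sample_id = samp[w], efficiency = e,
        f0 = f0, crossing_cycle = cross[w], threshold = thr,
        stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, curve_rows),
       truth = do.call(rbind, truth_rows))
}

#' Generate a ChIP-qPCR Ct experiment
#'
#' Inverts the percent-input relation exactly: for each locus,
#' `Ct_sample = Ct_input - log_E(percent_input / 100)` plus Gaussian Ct
#' noise; the mock fraction is generated the same way from
#' `mock_percent_input`. The injected per-locus truth is returned alongside.
#'
#' @param config A [sim_config()].
#' @param truth Optional data.frame (gene_id, antibody, percent_input);
#'   defaults to `config$true_percent_input`, or to a three-locus demo
#'   (bivalent, K4-only, unmarked) when that is NULL.
#' @return list(measurements = data.frame(gene_id, primer_id, antibody,
#'   efficiency, ct_input, ct_sample, ct_mock, mock_kind),
#'   truth = locus truth with mock_percent_input attached).
#' @export
generate_chip_experiment <- function(config, truth = NULL) {
  validate_sim_config(config)
  if (is.null(truth)) truth <- config$true_percent_input
  if (is.null(truth)) {
    pos <- config$percent_input_positive
    neg <- config$percent_input_negative
    truth <- data.frame(
      gene_id = rep(c("locus_biv", "locus_k4", "locus_off"), each = 2L),
      antibody = rep(c("H3K4me3", "H3K27me3"), 3L),
      percent_input = c(pos, pos, pos, neg, neg, neg),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "antibody", "percent_input") %in% names(truth)))
  if (any(truth$percent_input <= 0)) stop("true percent inputs must be positive")
  e <- config$chip_efficiency
  if (e <= 1 || e > 2) stop("invalid config: chip_efficiency must lie in (1, 2]")

  set.seed(config$seed + 41L)
  n <- nrow(truth)
  sdn <- config$chip_ct_noise_sd
  noise <- function() if (sdn > 0) rnorm(n, 0, sdn) else 0
  ct_input <- config$input_ct_mean + noise()
  ct_sample <- ct_input - log(truth$percent_input / 100) / log(e) + noise()
  ct_mock <- ct_input - log(config$mock_percent_input / 100) / log(e) + noise()
  mock_kind <- ifelse(truth$antibody == "PPARb", "ppar_mo_signal",
                      "empty_beads")
  meas <- data.frame(gene_id = truth$gene_id,
                     primer_id = paste0(truth$gene_id, "_pp"),
                     antibody = truth$antibody, efficiency = e,
                     ct_input = ct_input, ct_sample = ct_sample,
                     ct_mock = ct_mock, mock_kind = mock_kind,
                     stringsAsFactors = FALSE)
  truth$mock_percent_input <- config$mock_percent_input
  list(measurements = meas, truth = truth)
}

#' Generate a developmental expression time course
#'
#' Baseline genes follow a slowly varying log-normal random walk across
#' stages; burst genes jump by `burst_fold` over the designated gastrula
#' transition and persist at the high level thereafter.
#'
#' @param config A [sim_config()].
#' @return list(timecourse = [expression_timecourse()],
#'   truth = list(burst_genes)).
#' @export
generate_timecourse <- function(config) {
  validate_sim_config(config)
  if (length(config$stage_names) < 3L) stop("need at least 3 stages")
  set.seed(config$seed + 51L)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  stages <- config$stage_names
  from_i <- match(config$gastrula_transition[1], stages)
  to_i <- match(config$gastrula_transition[2], stages)
  if (is.na(from_i) || is.na(to_i) || to_i != from_i + 1L) {
    stop("gastrula_transition must name a consecutive stage pair")
  }
  n_burst <- round(config$burst_gene_fraction * n)
  burst <- if (n_burst > 0L) sample(genes, n_burst) else character(0)

  lv <- matrix(NA_real_, n, length(stages), dimnames = list(genes, stages))
  lv[, 1] <- rlnorm(n, config$mean_log_expression, config$sd_log_expression)
  for (s in 2:length(stages)) {
    step <- exp(rnorm(n, 0, config$timecourse_noise_sd))
    mult <- ifelse(genes %in% burst & s == to_i, config$burst_fold, 1)
    lv[, s] <- lv[, s - 1] * step * mult
  }
  list(timecourse = expression_timecourse(lv, config$stage_durations_h),
       truth = list(burst_genes = burst))
}

#' Generate cross-species ortholog chromatin states
#'
#' Each gene carries a true chromatin class (K27 / K4-only / unmarked) and a
#' promotion status; the K27-vs-promoted odds ratio equals
#' `k27_odds_ratio` in expectation with control-arm K27 prevalence
#' `k27_baseline_prob`. Each of the two species (mESC, zebrafish) reports
#' the true class with probability `conservation_prob`, otherwise a class
#' redrawn uniformly.
#'
#' @param config A [sim_config()].
#' @param genes Optional gene ids (default `sg0001`, ...).
#' @param promoted Optional logical vector aligned with `genes`; default:
#'   first `n_promoted_screen` genes promoted, next `n_control_screen` not.
#' @return list(states = data.frame(gene_id, species, k4, k27),
#'   truth = list(gene_k27_state, gene_promoted, gene_class)).
#' @export
generate_ortholog_states <- function(config, genes = NULL, promoted = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 61L)
  if (is.null(genes)) {
    n <- config$n_promoted_screen + config$n_control_screen
    genes <- sprintf("sg%04d", seq_len(n))
    promoted <- rep(c(TRUE, FALSE),
                    c(config$n_promoted_screen, config$n_control_screen))
  }
  stopifnot(length(promoted) == length(genes))
  n <- length(genes)

  p0 <- config$k27_baseline_prob
  odds1 <- config$k27_odds_ratio * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  k27 <- rbinom(n, 1L, ifelse(promoted, p1, p0)) == 1L
  class_true <- ifelse(k27, "K27",
                       ifelse(rbinom(n, 1L, config$k4_prob_nonk27) == 1L,
                              "K4_only", "unmarked"))

  species <- c("mESC", "zebrafish")
  rows <- lapply(species, function(sp) {
    keep <- runif(n) < config$conservation_prob
    cls <- ifelse(keep, class_true,
                  sample(c("K27", "K4_only", "unmarked"), n, replace = TRUE))
    k27_f <- cls == "K27"
    k4_f <- ifelse(k27_f, rbinom(n, 1L, config$k4_given_k27) == 1L,
                   cls == "K4_only")
    data.frame(gene_id = genes, species = sp, k4 = k4_f, k27 = k27_f,
               stringsAsFactors = FALSE)
  })
  list(states = do.call(rbind, rows),
       truth = list(gene_k27_state = setNames(k27, genes),
                    gene_promoted = setNames(promoted, genes),
                    gene_class = setNames(class_true, genes)))
}

#' Generate the H3K27me3 ChIP screen over promoted and control gene sets
#'
#' Couples [generate_ortholog_states()] (K27 truth with the configured odds
#' ratio to promotion) with [generate_chip_experiment()]: K27-true loci get
#' `percent_input_positive`, the rest `percent_input_negative`.
#'
#' @param config A [sim_config()].
#' @param promoted_genes,control_genes Optional gene-id vectors; defaults
#'   follow the configured screen sizes.
#' @return list(measurements, states, promoted_genes, control_genes, truth).
#' @export
generate_chip_screen <- function(config, promoted_genes = NULL,
                                 control_genes = NULL) {
  validate_sim_config(config)
  if (is.null(promoted_genes) != is.null(control_genes)) {
    stop("supply both gene sets or neither")
  }
  if (is.null(promoted_genes)) {
    states <- generate_ortholog_states(config)
  } else {
    genes <- c(promoted_genes, control_genes)
    if (anyDuplicated(genes)) stop("promoted and control sets must be disjoint")
    states <- generate_ortholog_states(
      config, genes = genes,
      promoted = rep(c(TRUE, FALSE),
                     c(length(promoted_genes), length(control_genes))))
  }
  k27 <- states$truth$gene_k27_state
  truth_pi <- data.frame(
    gene_id = names(k27), antibody = "H3K27me3",
    percent_input = ifelse(k27, config$percent_input_positive,
                           config$percent_input_negative),
    stringsAsFactors = FALSE)
  chip <- generate_chip_experiment(config, truth = truth_pi)
  promoted <- states$truth$gene_promoted
  list(measurements = chip$measurements, states = states$states,
       promoted_genes = names(promoted)[promoted],
       control_genes = names(promoted)[!promoted],
       truth = list(gene_k27_state = k27, gene_promoted = promoted,
                    percent_input = chip$truth))
}
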