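#' Simulation configuration
#'
#' Builds the configuration object shared by all synthetic-data generators.
#' The defaults define the study conditions the package emulates: a
#' morpholino (MO) knock-down transcriptome of 2000 genes with negative
#' binomial counts around log-normal means matched to typical tag-count
#' quartiles (Q1 ~ 26, median ~ 99, Q3 ~ 305), a global MO library-size
#' factor of 0.8, qPCR amplification efficiencies between 1.9 and 2.0, a
#' ChIP screen of 35 promoted versus 27 control genes, and an odds ratio of
#' 17 between H3K27me3 state and PPARbeta promotion (the control-arm K27
#' prevalence 0.04 mirrors the ~1/27 rate observed in unaffected genes).
#'
#' @param seed Integer seed; all generators derive their streams from it
#'   (identical configs yield byte-identical outputs).
#' @param n_genes Number of genes/transcripts in the simulated universe.
#' @param n_affected_down,n_affected_up Counts of genes with injected MO
#'   effects (down = PPARbeta-promoted, up = PPARbeta-repressed).
#' @param effect_fold_range Range of fold-change magnitudes for affected
#'   genes; a magnitude m becomes fold 1/m for down and m for up genes.
#' @param library_scale Global multiplicative factor applied to the MO
#'   library (ground truth for normalization).
#' @param nb_dispersion Negative binomial dispersion (size = 1/dispersion).
#' @param mean_log_expression,sd_log_expression Log-normal parameters of the
#'   per-gene mean expression.
#' @param transcript_length Length (nt) of each simulated transcript.
#' @param tag_length Length (nt) of each sequence tag.
#' @param stage_names Ordered developmental stage labels.
#' @param stage_durations_h Hours between consecutive stages
#'   (length = length(stage_names) - 1).
#' @param gastrula_transition Length-2 character vector naming the
#'   consecutive stage pair carrying the gastrula expression burst.
#' @param burst_gene_fraction Fraction of genes bursting at gastrula.
#' @param burst_fold Fold increase of burst genes (>= 4).
#' @param timecourse_noise_sd Log-scale random-walk sd per stage step.
#' @param true_efficiencies Named vector, primer -> amplification efficiency
#'   in (1, 2].
#' @param fmax Plateau fluorescence of the saturating curve model.
#' @param curve_baseline Constant fluorescence baseline added to all curves.
#' @param curve_noise_sd Gaussian curve noise, as a fraction of `fmax`.
#' @param curve_threshold_frac Detection threshold (fraction of `fmax`) at
#'   which the true crossing cycle of each synthetic curve is defined.
#' @param input_ct_mean Mean input-fraction Ct in the ChIP simulation.
#' @param chip_ct_noise_sd Gaussian sd (cycles) on simulated ChIP Cts.
#' @param chip_efficiency Amplification efficiency of ChIP primers.
#' @param percent_input_positive,percent_input_negative True percent input at
#'   marked and unmarked loci.
#' @param mock_percent_input True percent input of the negative-control
#'   (mock) fraction.
#' @param true_percent_input Optional data.frame (gene_id, antibody,
#'   percent_input) overriding the per-locus truth.
#' @param k27_odds_ratio Odds ratio between K27 state and PPARbeta promotion.
#' @param k27_baseline_prob K27 prevalence in the non-promoted (control) arm.
#' @param k4_given_k27 Probability that a K27 gene also carries H3K4me3
#'   (bivalent co-occupancy).
#' @param k4_prob_nonk27 Probability that a non-K27 gene is K4-only (else
#'   unmarked).
#' @param conservation_prob Probability that a species reproduces the gene's
#'   true chromatin class (else the class is redrawn at random).
#' @param n_promoted_screen,n_control_screen Gene-set sizes of the ChIP
#'   screen.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_affected_down = 100L,
                       n_affected_up = 50L,
                       effect_fold_range = c(2, 8),
                       library_scale = 0.8,
                       nb_dispersion = 0.1,
                       mean_log_expression = log(100),
                       sd_log_expression = 1.6,
                       transcript_length = 600L,
                       tag_length = 20L,
                       stage_names = c("st8", "st9", "st10.5", "st11",
                                       "st13", "st15", "st20", "st25"),
                       stage_durations_h = c(1.5, 2.5, 1.5, 3.5, 2.5, 4, 6),
                       gastrula_transition = c("st11", "st13"),
                       burst_gene_fraction = 0.025,
                       burst_fold = 8,
                       timecourse_noise_sd = 0.1,
                       true_efficiencies = c(EEF1a = 1.9, RPL8 = 1.95,
                                             target = 2.0),
                       fmax = 1,
                       curve_baseline = 0.02,
                       curve_noise_sd = 0,
                       curve_threshold_frac = 0.05,
                       input_ct_mean = 25,
                       chip_ct_noise_sd = 0.15,
                       chip_efficiency = 2,
                       percent_input_positive = 3,
                       percent_input_negative = 0.3,
                       mock_percent_input = 0.2,
                       true_percent_input = NULL,
                       k27_odds_ratio = 17,
                       k27_baseline_prob = 0.04,
                       k4_given_k27 = 0.6,
                       k4_prob_nonk27 = 0.7,
                       conservation_prob = 0.9,
                       n_promoted_screen = 35L,
                       n_control_screen = 27L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_affected_down = as.integer(n_affected_down),
              n_affected_up = as.integer(n_affected_up),
              effect_fold_range = as.numeric(effect_fold_range),
              library_scale = library_scale,
              nb_dispersion = nb_dispersion,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              transcript_length = as.integer(transcript_length),
              tag_length = as.integer(tag_length),
              stage_names = stage_names,
              stage_durations_h = stage_durations_h,
              gastrula_transition = gastrula_transition,
              burst_gene_fraction = burst_gene_fraction,
              burst_fold = burst_fold,
              timecourse_noise_sd = timecourse_noise_sd,
              true_efficiencies = true_efficiencies,
              fmax = fmax, curve_baseline = curve_baseline,
              curve_noise_sd = curve_noise_sd,
              curve_threshold_frac = curve_threshold_frac,
              input_ct_mean = input_ct_mean,
              chip_ct_noise_sd = chip_ct_noise_sd,
              chip_efficiency = chip_efficiency,
              percent_input_positive = percent_input_positive,
              percent_input_negative = percent_input_negative,
              mock_percent_input = mock_percent_input,
              true_percent_input = true_percent_input,
              k27_odds_ratio = k27_odds_ratio,
              k27_baseline_prob = k27_baseline_prob,
              k4_given_k27 = k4_given_k27,
              k4_prob_nonk27 = k4_prob_nonk27,
              conservation_prob = conservation_prob,
              n_promoted_screen = as.integer(n_promoted_screen),
              n_control_screen = as.integer(n_control_screen))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) {
    stop("invalid config: n_genes must be >= 1")
  }
  if (cfg$n_affected_down < 0L || cfg$n_affected_up < 0L ||
      cfg$n_affected_down + cfg$n_affected_up > cfg$n_genes) {
    stop("invalid config: n_affected_down + n_affected_up must not exceed n_genes")
  }
  if (any(cfg$effect_fold_range <= 0) || cfg$library_scale <= 0 ||
      cfg$burst_fold <= 0) {
    stop("invalid config: folds and scales must be strictly positive")
  }
  if (any(cfg$true_efficiencies <= 1) || any(cfg$true_efficiencies > 2)) {
    stop("invalid config: true efficiencies must lie in (1, 2]")
  }
  if (length(cfg$stage_durations_h) != length(cfg$stage_names) - 1L) {
    stop("invalid config: stage_durations_h must have length(stage_names) - 1 entries")
  }
  if (any(cfg$stage_durations_h <= 0)) {
    stop("invalid config: stage durations must be positive")
  }
  if (cfg$burst_gene_fraction < 0 || cfg$burst_gene_fraction > 1 ||
      cfg$conservation_prob < 0 || cfg$conservation_prob > 1) {
    stop("invalid config: proportions must lie in [0, 1]")
  }
  if (cfg$k27_odds_ratio <= 0) stop("invalid config: k27_odds_ratio must be > 0")
  if (cfg$transcript_length < 2L * cfg$tag_length + 10L) {
    stop("invalid config: transcript_length must be >= 2 * tag_length + 10")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes, seed", x$seed, "\n")
  cat("  MO effects:", x$n_affected_down, "down /", x$n_affected_up,
      "up; library scale", x$library_scale, "\n")
  cat("  screen:", x$n_promoted_screen, "promoted vs", x$n_control_screen,
      "controls; K27 odds ratio", x$k27_odds_ratio, "\n")
  invisible(x)
}
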