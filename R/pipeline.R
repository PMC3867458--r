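# End-to-end orchestration: simulate every input, run mapping,
# normalization, qPCR quantification, ChIP scoring, classification,
# enrichment testing and developmental dynamics, write the TSV/JSON
# outputs and a run manifest.

#' Pipeline configuration
#'
#' Stage parameters default to the published values where one exists
#' (separation 500 nt, 1 mismatch per tag, 5 N per pair, top 200
#' downregulated genes, percent input > 1%, enrichment > 5, fold
#' thresholds 2/4/8).
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param map_n_genes Transcript count of the toy mapping substrate.
#' @param n_pairs_per_transcript Tag pairs per transcript for mapping.
#' @param max_sep,max_mismatch Mapping filters.
#' @param pseudocount Fold pseudocount.
#' @param top_n Promoted-candidate set size.
#' @param unchanged_band Control-candidate fold band.
#' @param scale_factor Optional override of the normalization factor (e.g.
#'   a published value); NULL computes it from the data.
#' @param qpcr_window,qpcr_min_r2 Window-of-linearity parameters.
#' @param input_min,enr_min ChIP positivity thresholds.
#' @param fold_thresholds Developmental fold thresholds.
#' @param burst_min_fold Burst-set fold criterion.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            map_n_genes = 25L,
                            n_pairs_per_transcript = 8L,
                            max_sep = 500L, max_mismatch = 1L,
                            pseudocount = 0.5, top_n = 200L,
                            unchanged_band = c(0.9, 1.1),
                            scale_factor = NULL,
                            qpcr_window = 5L, qpcr_min_r2 = 0.99,
                            input_min = 1.0, enr_min = 5.0,
                            fold_thresholds = c(2, 4, 8),
                            burst_min_fold = 4) {
  cfg <- list(sim = sim, map_n_genes = as.integer(map_n_genes),
              n_pairs_per_transcript = as.integer(n_pairs_per_transcript),
              max_sep = max_sep, max_mismatch = max_mismatch,
              pseudocount = pseudocount, top_n = as.integer(top_n),
              unchanged_band = unchanged_band, scale_factor = scale_factor,
              qpcr_window = as.integer(qpcr_window),
              qpcr_min_r2 = qpcr_min_r2,
              input_min = input_min, enr_min = enr_min,
              fold_thresholds = fold_thresholds,
              burst_min_fold = burst_min_fold)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write every synthetic dataset to an output directory
#'
#' Emits the FASTA/TSV inputs the pipeline consumes, each with a JSON
#' ground-truth sidecar.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param map_n_genes,n_pairs_per_transcript Toy-scale mapping substrate.
#' @return Invisibly, the list of generated objects.
#' @export
simulate_datasets <- function(config = sim_config(), outdir,
                              map_n_genes = 25L,
                              n_pairs_per_transcript = 8L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  map_cfg <- config
  map_cfg$n_genes <- as.integer(map_n_genes)
  map_cfg$n_affected_down <- 0L
  map_cfg$n_affected_up <- 0L
  tx <- generate_transcriptome(map_cfg)
  write_transcripts_fasta(tx, p("transcripts.fa"))
  pairs <- generate_tag_pairs(tx, n_pairs_per_transcript,
                              seed = config$seed + 12L,
                              tag_length = config$tag_length)
  write_tsv(pairs, p("tag_pairs.tsv"))

  counts <- generate_count_experiment(config)
  write_tsv(counts$counts, p("counts.tsv"))
  write_json_sidecar(counts$truth, p("counts.truth.json"))

  curves <- generate_amplification_curves(config)
  write_tsv(curves$curves, p("qpcr_curves.tsv"))
  write_tsv(curves$truth, p("qpcr_curves.truth.tsv"))

  screen <- generate_chip_screen(config)
  write_tsv(screen$measurements, p("chip_cts.tsv"))
  write_tsv(screen$states, p("epi_states.tsv"))
  write_gene_set(screen$promoted_genes, p("promoted_genes.txt"))
  write_gene_set(screen$control_genes, p("control_genes.txt"))
  write_json_sidecar(screen$truth, p("chip_screen.truth.json"))

  tc <- generate_timecourse(config)
  lv <- data.frame(gene_id = rownames(tc$timecourse$levels),
                   tc$timecourse$levels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(lv, p("timecourse.tsv"))
  write_tsv(data.frame(from = head(tc$timecourse$stages, -1),
                       to = tc$timecourse$stages[-1],
                       duration_h = tc$timecourse$durations_h),
            p("stage_durations.tsv"))
  write_json_sidecar(tc$truth, p("timecourse.truth.json"))

  invisible(list(transcripts = tx, pairs = pairs, counts = counts,
                 curves = curves, screen = screen, timecourse = tc))
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes simulate, map-tags, normalize/rank, qPCR efficiency and
#' quantities, ChIP scoring, classification, enrichment test and
#' developmental rates; writes every stage output plus a run manifest
#' (config snapshot, per-stage record counts, output checksums).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, list(results, manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  counts_rec <- list()

  # 1. simulate
  sim <- simulate_datasets(config$sim, outdir,
                           map_n_genes = config$map_n_genes,
                           n_pairs_per_transcript = config$n_pairs_per_transcript)
  counts_rec$simulate <- nrow(sim$counts$counts)

  # 2. map-tags (toy scale)
  mapped <- map_pairs(sim$pairs, sim$transcripts,
                      max_sep = config$max_sep,
                      max_mismatch = config$max_mismatch)
  write_tsv(mapped$hits, p("tag_hits.tsv"))
  write_tsv(mapped$rejections, p("tag_rejections.tsv"))
  tag_counts <- count_tags(mapped$hits, sim$transcripts)
  write_tsv(data.frame(transcript_id = names(tag_counts),
                       n_pairs = as.integer(tag_counts)),
            p("tag_counts.tsv"))
  counts_rec$map_tags <- nrow(mapped$hits)

  # 3. normalize / rank / gene sets
  factor <- if (is.null(config$scale_factor)) {
    distribution_scale_factor(sim$counts$counts)
  } else config$scale_factor
  norm <- apply_scale(sim$counts$counts, factor)
  write_tsv(data.frame(condition = rownames(norm$summary), norm$summary,
                       check.names = FALSE),
            p("count_summary.tsv"))
  reg <- relative_abundance(norm, pseudocount = config$pseudocount)
  write_tsv(reg, p("regulation.tsv"))
  sets <- select_gene_sets(reg, top_n = config$top_n,
                           unchanged_band = config$unchanged_band)
  write_gene_set(sets$promoted_candidates, p("promoted_candidates.txt"))
  write_gene_set(sets$control_candidates, p("control_candidates.txt"))
  counts_rec$normalize <- nrow(reg)

  # 4. qPCR efficiencies and relative quantities
  thr <- config$sim$curve_threshold_frac * config$sim$fmax
  eff <- estimate_efficiencies(sim$curves$curves,
                               window = config$qpcr_window,
                               min_r2 = config$qpcr_min_r2)
  write_tsv(data.frame(primer_id = names(eff), efficiency = unname(eff)),
            p("primer_efficiencies.tsv"))
  cts <- call_cts(sim$curves$curves, threshold = thr)
  write_tsv(cts, p("qpcr_cts.tsv"))
  counts_rec$qpcr <- length(eff)

  # 5. ChIP scoring of the screen
  screen <- screen_gene_sets(sim$screen$measurements,
                             sim$screen$promoted_genes,
                             sim$screen$control_genes,
                             input_min = config$input_min,
                             enr_min = config$enr_min)
  write_tsv(screen$calls, p("mark_calls.tsv"))
  write_json_sidecar(as.list(screen$counts), p("screen_counts.json"))
  counts_rec$chip_score <- nrow(screen$calls)

  # 6. classification from ortholog states
  classes <- conserved_classes(sim$screen$states)
  write_tsv(classes, p("gene_classes.tsv"))
  counts_rec$classify <- nrow(classes)

  # 7. enrichment test
  ct <- screen$contingency
  fish <- fisher_exact_2x2(ct["a"], ct["b"], ct["c"], ct["d"])
  write_json_sidecar(list(table = as.list(ct),
                          odds_ratio = fish$odds_ratio,
                          p_two_sided = fish$p_two_sided,
                          p_one_sided_greater = fish$p_one_sided_greater),
                     p("fisher_report.json"))
  counts_rec$enrich_test <- 1L

  # 8. developmental dynamics
  tc <- sim$timecourse$timecourse
  rates <- transition_rates(tc, thresholds = config$fold_thresholds)
  write_tsv(rates, p("transition_rates.tsv"))
  bs <- burst_set(tc, config$sim$gastrula_transition[1],
                  config$sim$gastrula_transition[2],
                  min_fold = config$burst_min_fold)
  write_gene_set(bs, p("burst_genes.txt"))
  write_tsv(persistence_profile(tc, bs), p("burst_persistence.tsv"))
  counts_rec$dev_rates <- nrow(rates)

  overlap <- overlap_summary(sets$promoted_candidates,
                             classes$gene_id[!is.na(classes$class) &
                                             classes$class == "K27"],
                             bs, labels = c("promoted", "K27", "burst"))
  write_json_sidecar(as.list(overlap), p("overlap_summary.json"))

  outputs <- setdiff(list.files(outdir, full.names = TRUE),
                     p("run_manifest.json"))
  manifest <- list(
    seed = config$sim$seed,
    parameters = config[setdiff(names(config), "sim")],
    stage_record_counts = counts_rec,
    output_md5 = as.list(tools::md5sum(sort(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json_sidecar(manifest, p("run_manifest.json"))

  results <- list(mapped = mapped, tag_counts = tag_counts,
                  normalization = norm, regulation = reg, gene_sets = sets,
                  efficiencies = eff, cts = cts, screen = screen,
                  classes = classes, fisher = fish, rates = rates,
                  burst_genes = bs, overlap = overlap, sim = sim)
  invisible(list(results = results, manifest = manifest))
}
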