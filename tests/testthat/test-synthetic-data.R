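# The generators must be deterministic under a fixed config, emit their
# ground truth, and reproduce the study conditions they claim to emulate.

test_that("transcriptome generation is deterministic and well formed", {
  cfg <- small_config(seed = 1, n_genes = 5)
  tx1 <- generate_transcriptome(cfg)
  tx2 <- generate_transcriptome(cfg)
  expect_identical(tx1, tx2)
  expect_identical(names(tx1), sprintf("t%04d", 1:5))
  expect_true(all(nchar(tx1) == cfg$transcript_length))
  expect_false(identical(tx1, generate_transcriptome(small_config(seed = 2,
                                                                  n_genes = 5))))
  expect_error(sim_config(n_genes = 0), "invalid config")
})

test_that("transcriptome base composition is uniform (GC near 0.5)", {
  tx <- generate_transcriptome(small_config(seed = 7, n_genes = 100))
  chars <- strsplit(paste(tx, collapse = ""), "", fixed = TRUE)[[1]]
  gc <- mean(chars %in% c("G", "C"))
  # binomial bound: 60000 bases, sd ~ 0.002; 0.45-0.55 is > 20 sd wide
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)
})

test_that("tag pairs carry provenance and corruption flags", {
  tx <- generate_transcriptome(small_config(seed = 3, n_genes = 5))
  pairs <- generate_tag_pairs(tx, 4, seed = 11)
  expect_true(all(!is.na(pairs$source_transcript)))   # no decoys
  # no corruption: tags match their recorded source positions exactly
  for (i in seq_len(nrow(pairs))) {
    src <- tx[[pairs$source_transcript[i]]]
    tl <- nchar(pairs$tag1[i])
    expect_identical(pairs$tag1[i],
                     substr(src, pairs$pos1[i] + 1, pairs$pos1[i] + tl))
    expect_identical(pairs$tag2[i],
                     revcomp_chr(substr(src, pairs$pos2[i] + 1,
                                        pairs$pos2[i] + tl)))
    expect_lte(pairs$separation[i], 500L)
  }
  expect_identical(pairs, generate_tag_pairs(tx, 4, seed = 11))

  # heavy N masking: pairs exceeding 5 Ns are pre-labelled as filtered
  noisy <- generate_tag_pairs(tx, 10, n_rate = 0.4, seed = 12)
  expect_true(any(noisy$n_count > 5))
  expect_identical(noisy$expected_filtered, noisy$n_count > 5L)

  dec <- generate_tag_pairs(tx, 4, decoy_fraction = 0.2, seed = 13)
  expect_true(any(dec$is_decoy))
  expect_true(all(is.na(dec$source_transcript[dec$is_decoy])))
})

test_that("count experiment injects folds and scale as recorded truth", {
  # null configuration: log-fold distribution centred at 0
  ce0 <- generate_count_experiment(small_config(seed = 5, n_genes = 2000,
                                                library_scale = 1))
  lf <- with(ce0$counts, log2((MO + 0.5) / (Co + 0.5)))
  expect_lt(abs(median(lf)), 0.05)
  expect_length(ce0$truth$affected_genes, 0)

  # injected downregulation is bookkept
  cfg <- sim_config(seed = 6, n_genes = 500, n_affected_down = 100,
                    n_affected_up = 0, effect_fold_range = c(4, 4))
  ce <- generate_count_experiment(cfg)
  expect_length(ce$truth$affected_genes, 100)
  expect_true(all(abs(ce$truth$affected_genes - 0.25) < 1e-12))
  expect_true(all(names(ce$truth$affected_genes) %in% ce$counts$gene_id))
  expect_identical(ce$counts,
                   generate_count_experiment(cfg)$counts)
})

test_that("amplification curves follow the saturating exponential model", {
  for (e in c(2.0, 1.8)) {
    cfg <- small_config(seed = 4, n_genes = 5,
                        true_efficiencies = c(pp = e), curve_noise_sd = 0)
    cur <- generate_amplification_curves(cfg, n_wells_per_primer = 1,
                                         crossing_cycles = 20)
    cc <- cur$curves[order(cur$curves$cycle), ]
    sig <- cc$fluorescence - cfg$curve_baseline
    # pre-saturation phase: slope of log10 fluorescence = log10(E)
    pre <- 6:12
    slopes <- diff(log10(sig[pre]))
    expect_true(all(abs(slopes - log10(e)) < 1e-3))
    expect_equal(cur$truth$crossing_cycle, 20)
    # recorded truth is consistent with the closed-form crossing
    expect_equal(true_crossing_cycle(cur$truth$f0, e, cfg$fmax,
                                     cur$truth$threshold), 20)
  }
  noisy <- generate_amplification_curves(
    small_config(seed = 4, n_genes = 5, curve_noise_sd = 0.01,
                 true_efficiencies = c(pp = 1.9)), n_wells_per_primer = 8)
  expect_identical(nrow(noisy$truth), 8L)
  expect_true(all(is.finite(noisy$truth$f0)))
})

test_that("ChIP Ct generation inverts the percent-input relation", {
  mk <- function(pi, seed = 5) {
    truth <- data.frame(gene_id = "g1", antibody = "H3K27me3",
                        percent_input = pi)
    generate_chip_experiment(small_config(seed = seed, n_genes = 5,
                                          chip_ct_noise_sd = 0),
                             truth = truth)$measurements
  }
  m100 <- mk(100)
  expect_equal(m100$ct_sample, m100$ct_input)
  m25 <- mk(25)
  expect_equal(m25$ct_sample, m25$ct_input + 2)     # E = 2, log2(4) cycles
})

test_that("boundary locus (1% input, enrichment 1) scores negative downstream", {
  cfg <- small_config(seed = 8, n_genes = 5, chip_ct_noise_sd = 0,
                      mock_percent_input = 1.0)
  truth <- data.frame(gene_id = "g1", antibody = "H3K27me3",
                      percent_input = 1.0)
  m <- generate_chip_experiment(cfg, truth = truth)$measurements
  call <- score_mark(m)
  expect_equal(call$percent_input, 1.0)
  expect_equal(call$enrichment, 1.0)
  expect_false(call$positive)
})

test_that("time course bursts at the designated transition and persists", {
  # null: no burst genes, small noise -> no 4x transitions
  tc0 <- generate_timecourse(small_config(seed = 9, n_genes = 500,
                                          burst_gene_fraction = 0))
  expect_length(tc0$truth$burst_genes, 0)
  expect_length(burst_set(tc0$timecourse, "st11", "st13"), 0)

  cfg <- small_config(seed = 10, n_genes = 500, burst_gene_fraction = 0.05,
                      burst_fold = 8, timecourse_noise_sd = 0.05)
  tc <- generate_timecourse(cfg)
  bs <- burst_set(tc$timecourse, "st11", "st13", min_fold = 4)
  expect_true(all(tc$truth$burst_genes %in% bs))
  # burst genes maintain >= 50% of their peak level at all later stages
  lv <- tc$timecourse$levels[tc$truth$burst_genes, , drop = FALSE]
  peak_i <- match("st13", tc$timecourse$stages)
  later <- lv[, peak_i:ncol(lv), drop = FALSE]
  expect_true(all(later >= 0.5 * lv[, peak_i]))
})

test_that("ortholog states reproduce the configured association", {
  # null odds ratio at large n: sample log-OR near 0
  cfg1 <- small_config(seed = 11, n_genes = 5, k27_odds_ratio = 1,
                       k27_baseline_prob = 0.3)
  st <- generate_ortholog_states(cfg1, genes = sprintf("g%04d", 1:4000),
                                 promoted = rep(c(TRUE, FALSE), 2000))
  k27 <- st$truth$gene_k27_state
  prom <- st$truth$gene_promoted
  or_hat <- (sum(k27 & prom) * sum(!k27 & !prom)) /
    (sum(!k27 & prom) * sum(k27 & !prom))
  expect_lt(abs(log(or_hat)), 0.5)

  # full conservation: every K27/K4-only gene is a conserved call
  cfg2 <- small_config(seed = 12, n_genes = 5, conservation_prob = 1)
  st2 <- generate_ortholog_states(cfg2)
  cc <- conserved_classes(st2$states)
  truth_class <- st2$truth$gene_class[cc$gene_id]
  expect_identical(cc$conserved, unname(truth_class != "unmarked"))
  expect_identical(cc$class[cc$conserved],
                   unname(truth_class[truth_class != "unmarked"]))
})
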