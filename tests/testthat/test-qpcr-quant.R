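# Ct calling, window-of-linearity efficiency estimation and
# reference-normalized relative quantities.

curves_for <- function(e, noise = 0, wells = 1L, crossing = 20,
                       seed = 41, samples = NULL) {
  cfg <- small_config(seed = seed, n_genes = 5,
                      true_efficiencies = setNames(e, "pp"),
                      curve_noise_sd = noise)
  generate_amplification_curves(cfg, n_wells_per_primer = wells,
                                crossing_cycles = crossing,
                                sample_ids = samples)
}

test_that("Ct calling recovers the true crossing cycle", {
  cur <- curves_for(2.0, crossing = 20)
  cc <- cur$curves
  ct <- call_ct(cc$cycle, cc$fluorescence, threshold = 0.05)
  expect_lt(abs(ct - 20), 0.05)
  # threshold above the curve maximum: no-amplification flag
  expect_true(is.na(call_ct(cc$cycle, cc$fluorescence, threshold = 2)))
  # doubling the template advances the crossing by one cycle at E = 2
  cur2 <- curves_for(2.0, crossing = 19)     # F0 doubled <=> crossing - 1
  ct2 <- call_ct(cur2$curves$cycle, cur2$curves$fluorescence, 0.05)
  expect_lt(abs((ct - ct2) - 1), 0.05)
})

test_that("noise-free efficiency estimates are exact to 0.01", {
  for (e in c(2.0, 1.8)) {
    cur <- curves_for(e, wells = 4L, crossing = c(18, 20, 21, 23))
    est <- estimate_efficiency(cur$curves)
    expect_lt(abs(est$efficiency - e), 0.01)
    expect_identical(est$n_wells_used, 4L)
  }
})

test_that("noisy efficiency estimates recover truth within 0.05", {
  cur <- curves_for(1.9, noise = 0.005, wells = 8L,
                    crossing = NULL, seed = 43)
  est <- estimate_efficiency(cur$curves)
  expect_lt(abs(est$efficiency - 1.9), 0.05)
})

test_that("efficiency estimation is invariant to fluorescence rescaling", {
  cur <- curves_for(1.9, noise = 0.003, wells = 6L, seed = 44)
  scaled <- cur$curves
  scaled$fluorescence <- scaled$fluorescence * 13.7
  expect_equal(estimate_efficiency(cur$curves)$efficiency,
               estimate_efficiency(scaled)$efficiency)
})

test_that("efficiency estimation fails loudly on flat curves", {
  flat <- data.frame(well_id = "w1", primer_id = "dead", cycle = 1:40,
                     fluorescence = rep(0.02, 40))
  expect_error(estimate_efficiency(flat), "dead")
})

test_that("relative quantities follow E^(calibrator - Ct)", {
  ct <- data.frame(gene_id = "g", sample_id = c("a", "b"), ct = c(20, 20))
  expect_equal(relative_quantity(ct, 1.9)$rq, c(1, 1))
  ct2 <- data.frame(gene_id = "g", sample_id = c("a", "b"), ct = c(19, 21))
  rq <- relative_quantity(ct2, 2)
  expect_equal(rq$rq, c(2, 0.5))                     # delta to calibrator 20
  ct3 <- data.frame(gene_id = "g", sample_id = c("a", "b"),
                    ct = c(20.5, 19.5))
  expect_equal(relative_quantity(ct3, 1.9)$rq, c(1 / sqrt(1.9), sqrt(1.9)))
  expect_error(relative_quantity(ct, 0.9), "must be > 1")
  ct4 <- data.frame(gene_id = "g", sample_id = c("a", "b", "c"),
                    ct = c(20, NA, 22))
  expect_message(out <- relative_quantity(ct4, 2), "skipping")
  expect_identical(out$sample_id, c("a", "c"))
})

test_that("reference normalization divides by the geometric mean", {
  rq <- data.frame(gene_id = rep(c("EEF1a", "RPL8", "tgt"), 2),
                   sample_id = rep(c("s1", "s2"), each = 3),
                   rq = c(1, 1, 5, 2, 2, 5))
  norm <- normalize_to_references(rq)
  # both references doubled in s2: its target is halved
  tgt <- norm[norm$gene_id == "tgt", ]
  expect_equal(tgt$rq_norm, c(5, 2.5))
  # one reference x4, the other x1: geometric mean 2
  rq2 <- rq
  rq2$rq[rq2$sample_id == "s2" & rq2$gene_id == "EEF1a"] <- 4
  rq2$rq[rq2$sample_id == "s2" & rq2$gene_id == "RPL8"] <- 1
  tgt2 <- normalize_to_references(rq2)
  expect_equal(tgt2$rq_norm[tgt2$gene_id == "tgt"], c(5, 2.5))
  # idempotent: renormalizing changes nothing
  again <- normalize_to_references(
    data.frame(gene_id = norm$gene_id, sample_id = norm$sample_id,
               rq = norm$rq_norm))
  expect_equal(again$rq_norm, norm$rq_norm)
  expect_error(normalize_to_references(rq[rq$gene_id != "RPL8", ]), "RPL8")
})

test_that("replicate folds summarize MO/Co with SEM", {
  norm <- data.frame(gene_id = "g",
                     sample_id = c("co1", "mo1", "co2", "mo2"),
                     rq_norm = c(1, 0.25, 1, 0.26))
  info <- data.frame(sample_id = c("co1", "mo1", "co2", "mo2"),
                     condition = c("Co", "MO", "Co", "MO"),
                     replicate = c(1, 1, 2, 2))
  f <- fold_mo_vs_co(norm, info)
  expect_equal(f$mean_fold, 0.255)
  expect_equal(f$sem, sd(c(0.25, 0.26)) / sqrt(2))
  # identical conditions: fold 1, SEM 0
  same <- norm
  same$rq_norm <- 1
  expect_equal(fold_mo_vs_co(same, info)$mean_fold, 1)
  expect_equal(fold_mo_vs_co(same, info)$sem, 0)
  # a single replicate reports no SEM
  one <- fold_mo_vs_co(norm[1:2, ], info[1:2, ])
  expect_identical(one$n_replicates, 1L)
  expect_true(is.na(one$sem))
})

test_that("the curve-to-fold round trip recovers an injected knockdown", {
  # 4 replicates of a 4x knockdown at the target; references unchanged
  cfg <- small_config(seed = 45, n_genes = 5, curve_noise_sd = 0.002)
  samples <- paste0(rep(c("co", "mo"), 4), rep(1:4, each = 2))
  mk <- function(primer, e, cross) {
    cfg2 <- cfg
    cfg2$true_efficiencies <- setNames(e, primer)
    generate_amplification_curves(cfg2, n_wells_per_primer = 8L,
                                  crossing_cycles = cross,
                                  sample_ids = samples)$curves
  }
  # target crosses 2 cycles later in MO (fold 0.25 at E = 2)
  curves <- rbind(mk("EEF1a", 1.9, 20), mk("RPL8", 1.95, 21),
                  mk("target", 2.0, rep(c(20, 22), 4)))
  eff <- estimate_efficiencies(curves)
  cts <- call_cts(curves, threshold = 0.05)
  ct_table <- data.frame(gene_id = cts$primer_id, sample_id = cts$sample_id,
                         ct = cts$ct)
  rq <- relative_quantities(ct_table, eff)
  norm <- normalize_to_references(rq)
  info <- data.frame(sample_id = samples,
                     condition = rep(c("Co", "MO"), 4),
                     replicate = rep(1:4, each = 2))
  folds <- fold_mo_vs_co(norm, info)
  tgt <- folds[folds$gene_id == "target", ]
  expect_gt(tgt$mean_fold, 0.20)
  expect_lt(tgt$mean_fold, 0.32)
})
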