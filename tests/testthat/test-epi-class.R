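# Chromatin-class assignment, conservation calls, contingency building and
# the internal Fisher exact test against enumeration oracles.

test_that("classification: K27 dominates regardless of K4 co-occupancy", {
  expect_identical(classify_gene(TRUE, TRUE), "K27")
  expect_identical(classify_gene(FALSE, TRUE), "K27")
  expect_identical(classify_gene(TRUE, FALSE), "K4_only")
  expect_identical(classify_gene(FALSE, FALSE), "unmarked")
})

test_that("conservation requires identical K27/K4-only calls in both species", {
  st <- data.frame(
    gene_id = c("a", "a", "b", "b", "c", "d", "d"),
    species = c("mESC", "zebrafish", "mESC", "zebrafish", "mESC",
                "mESC", "zebrafish"),
    k4 = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    k27 = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  cc <- conserved_classes(st)
  rownames(cc) <- cc$gene_id
  expect_true(cc["a", "conserved"])                  # K27 in both
  expect_identical(cc["a", "class"], "K27")
  expect_true(cc["b", "conserved"])                  # K4-only in both
  # single species present: class retained, not conserved
  expect_false(cc["c", "conserved"])
  expect_identical(cc["c", "class"], "K27")
  # unmarked in both species does not count as a conserved signature
  expect_false(cc["d", "conserved"])
  expect_identical(cc["d", "class"], "unmarked")
  # disagreement: not conserved, K27 evidence wins in the combined class
  st2 <- data.frame(gene_id = c("e", "e"),
                    species = c("mESC", "zebrafish"),
                    k4 = c(TRUE, FALSE), k27 = c(FALSE, TRUE))
  cc2 <- conserved_classes(st2)
  expect_false(cc2$conserved)
  expect_identical(cc2$class, "K27")
  expect_error(conserved_classes(rbind(st, st[1, ])), "one row per")
  single <- conserved_class(st, "c")
  expect_identical(single$class, "K27")
  expect_false(single$conserved)
})

test_that("contingency building cross-tabulates calls by gene set", {
  calls <- data.frame(gene_id = c(sprintf("p%02d", 1:35),
                                  sprintf("c%02d", 1:27)),
                      positive = c(rep(TRUE, 14), rep(FALSE, 21),
                                   TRUE, rep(FALSE, 26)))
  ct <- build_contingency(sprintf("p%02d", 1:35), sprintf("c%02d", 1:27),
                          calls)
  expect_identical(unname(ct), c(14L, 21L, 1L, 26L))
  none <- build_contingency("p01", "c01",
                            data.frame(gene_id = c("p01", "c01"),
                                       positive = FALSE))
  expect_identical(unname(none), c(0L, 1L, 0L, 1L))
  expect_error(build_contingency(c("x", "y"), c("y"), calls), "both sets")
  expect_error(build_contingency("zz", "c01", calls), "without a mark call")
})

test_that("fisher test matches the published screen and the balanced null", {
  res <- fisher_exact_2x2(14, 21, 1, 26)
  expect_lt(res$p_two_sided, 0.005)
  expect_lt(res$p_one_sided_greater, 0.005)
  expect_equal(res$odds_ratio, (14 * 26) / (21 * 1))
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_two_sided, 1)
  # degenerate margin: conventional p = 1, flagged
  deg <- fisher_exact_2x2(0, 0, 3, 4)
  expect_true(deg$degenerate)
  expect_equal(deg$p_two_sided, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  # matrix input
  expect_equal(fisher_exact_2x2(matrix(c(14, 21, 1, 26), 2,
                                       byrow = TRUE))$p_two_sided,
               res$p_two_sided)
  expect_true(is.infinite(fisher_exact_2x2(5, 0, 1, 7)$odds_ratio))
})

test_that("fisher test equals full enumeration on small tables", {
  # exhaustive over all tables with total <= 14
  for (n in 1:14) {
    comps <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    comps <- comps[comps$a + comps$b + comps$c <= n, ]
    for (r in seq_len(nrow(comps))) {
      a <- comps$a[r]; b <- comps$b[r]; c_ <- comps$c[r]
      d <- n - a - b - c_
      got <- fisher_exact_2x2(a, b, c_, d)
      if (got$degenerate) next
      want <- oracle_fisher(a, b, c_, d)
      expect_equal(got$p_two_sided, want$p_two_sided, tolerance = 1e-10)
      expect_equal(got$p_one_sided_greater, want$p_one_sided_greater,
                   tolerance = 1e-10)
    }
  }
})

test_that("fisher test agrees with enumeration and stats::fisher.test on random tables", {
  set.seed(71)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 5, 9), 1))
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    if (got$degenerate) next
    want <- oracle_fisher(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_two_sided, want$p_two_sided, tolerance = 1e-10)
    expect_equal(got$p_one_sided_greater, want$p_one_sided_greater,
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(got$p_two_sided, ft$p.value, tolerance = 1e-6)
  }
})

test_that("overlap summary equals inclusion-exclusion set algebra", {
  o <- overlap_summary(c("a", "b"), c("c", "d"), c("e"),
                       labels = c("X", "Y", "Z"))
  expect_identical(unname(o[c("X_Y", "X_Z", "Y_Z", "X_Y_Z")]),
                   rep(0L, 4))
  o2 <- overlap_summary(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_identical(unname(o2[["A_B_C"]]), 2L)
  expect_identical(unname(o2[["A_only"]]), 0L)
  set.seed(72)
  for (i in 1:20) {
    u <- sprintf("g%02d", 1:30)
    sa <- sample(u, 12)
    sb <- sample(u, 9)
    sc <- sample(u, 15)
    o3 <- overlap_summary(sa, sb, sc)
    # inclusion-exclusion oracle for the triple intersection
    expect_identical(unname(o3[["A_B_C"]]),
                     length(intersect(intersect(sa, sb), sc)))
    expect_identical(unname(o3[["A_only"]]),
                     length(setdiff(setdiff(sa, sb), sc)))
    expect_identical(unname(o3[["A_B"]]),
                     length(setdiff(intersect(sa, sb), sc)))
    # regions partition the union
    expect_identical(sum(o3[1:7]), length(union(union(sa, sb), sc)))
  }
})
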