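# ChIP-qPCR scoring: percent input from the efficiency-corrected Ct
# difference, enrichment over the negative control, the two-criterion
# positivity rule (percent input > 1% AND enrichment over mock > 5, both
# strict), bivalency calls and gene-set screening.

#' Percent input from input and IP Cts
#'
#' `percent_input = E^(Ct_input - Ct_sample) * 100`.
#'
#' @param efficiency Gene-specific amplification efficiency E > 1
#'   (vectorized).
#' @param ct_input,ct_sample Threshold cycles of the input fraction and the
#'   immunoprecipitated sample.
#' @return Percent of input (100 means all of the input material).
#' @export
percent_input <- function(efficiency, ct_input, ct_sample) {
  if (any(efficiency <= 1)) stop("invalid efficiency: E must be > 1")
  efficiency^(ct_input - ct_sample) * 100
}

#' Enrichment of the IP over the negative control
#'
#' @param percent_input_ip,percent_input_mock Percent-input values of the
#'   IP and of the negative-control (mock) fraction.
#' @return Ratio IP / mock.
#' @export
enrichment <- function(percent_input_ip, percent_input_mock) {
  if (any(percent_input_mock == 0)) {
    stop("undefined enrichment: mock percent input is zero")
  }
  if (any(percent_input_ip < 0) || any(percent_input_mock < 0)) {
    stop("percent inputs must be non-negative")
  }
  percent_input_ip / percent_input_mock
}

#' Score chromatin-mark positivity from ChIP Ct measurements
#'
#' Computes percent input for the IP and the mock, their ratio, and calls a
#' locus positive iff `percent_input > input_min` AND
#' `enrichment > enr_min` -- both strictly. The negative-control convention
#' is carried through (`empty_beads` for histone marks,
#' `ppar_mo_signal` for PPARbeta ChIP).
#'
#' @param measurements data.frame with columns gene_id, antibody,
#'   efficiency, ct_input, ct_sample, ct_mock (and optionally mock_kind,
#'   primer_id).
#' @param input_min Percent-input threshold (default 1.0).
#' @param enr_min Enrichment threshold (default 5.0).
#' @return data.frame of mark calls: gene_id, antibody, percent_input,
#'   percent_input_mock, enrichment, positive, input_min, enr_min.
#' @export
score_mark <- function(measurements, input_min = 1.0, enr_min = 5.0) {
  need <- c("gene_id", "antibody", "efficiency", "ct_input", "ct_sample",
            "ct_mock")
  stopifnot(all(need %in% names(measurements)))
  pi_ip <- percent_input(measurements$efficiency, measurements$ct_input,
                         measurements$ct_sample)
  pi_mock <- percent_input(measurements$efficiency, measurements$ct_input,
                           measurements$ct_mock)
  enr <- enrichment(pi_ip, pi_mock)
  data.frame(gene_id = measurements$gene_id,
             antibody = measurements$antibody,
             mock_kind = if ("mock_kind" %in% names(measurements))
               measurements$mock_kind else NA_character_,
             percent_input = pi_ip, percent_input_mock = pi_mock,
             enrichment = enr,
             positive = pi_ip > input_min & enr > enr_min,
             input_min = input_min, enr_min = enr_min,
             stringsAsFactors = FALSE)
}

#' Bivalency call from paired H3K4me3 and H3K27me3 mark calls
#'
#' A locus is bivalent iff both marks are scored positive at the same gene.
#'
#' @param k4,k27 One-row mark calls (from [score_mark()]) for the H3K4me3
#'   and H3K27me3 antibodies at the same gene.
#' @return TRUE iff both calls are positive.
#' @export
call_bivalent <- function(k4, k27) {
  stopifnot(nrow(k4) == 1L, nrow(k27) == 1L)
  if (k4$gene_id != k27$gene_id) {
    stop("invalid pairing: calls refer to different genes")
  }
  if (k4$antibody != "H3K4me3" || k27$antibody != "H3K27me3") {
    stop("invalid pairing: expected H3K4me3 and H3K27me3 calls")
  }
  isTRUE(k4$positive && k27$positive)
}

#' Screen promoted and control gene sets for a chromatin mark
#'
#' Applies [score_mark()] to every measurement and tabulates positives in
#' the promoted and control sets, yielding the 2x2 counts that feed the
#' enrichment test.
#'
#' @param measurements ChIP measurement table (one row per screened gene).
#' @param promoted_set,control_set Disjoint gene-id vectors; every gene must
#'   be measured.
#' @param input_min,enr_min Positivity thresholds.
#' @return list(calls, counts = c(promoted_positive, promoted_total,
#'   control_positive, control_total), contingency =
#'   c(a, b, c, d)) where the contingency rows are promoted/control and the
#'   columns mark-positive/negative.
#' @export
screen_gene_sets <- function(measurements, promoted_set, control_set,
                             input_min = 1.0, enr_min = 5.0) {
  overlap <- intersect(promoted_set, control_set)
  if (length(overlap)) {
    stop("gene(s) in both sets: ", paste(overlap, collapse = ", "))
  }
  unmeasured <- setdiff(c(promoted_set, control_set), measurements$gene_id)
  if (length(unmeasured)) {
    stop("unmeasured gene(s): ", paste(unmeasured, collapse = ", "))
  }
  calls <- score_mark(measurements, input_min = input_min, enr_min = enr_min)
  pos <- calls$gene_id[calls$positive]
  a <- sum(promoted_set %in% pos)
  c_ <- sum(control_set %in% pos)
  list(calls = calls,
       counts = c(promoted_positive = a,
                  promoted_total = length(promoted_set),
                  control_positive = c_,
                  control_total = length(control_set)),
       contingency = c(a = a, b = length(promoted_set) - a,
                       c = c_, d = length(control_set) - c_))
}
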