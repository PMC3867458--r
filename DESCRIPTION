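Package: gastromark
Title: Bivalent Chromatin Screening and qPCR Quantification at Xenopus
    Gastrulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reproduce, on synthetic data with injected ground
    truth, the computational chain behind a screen for H3K27me3-marked
    genes preferentially activated by the nuclear receptor PPARbeta at
    Xenopus gastrulation: paired-end tag mapping onto a transcript set
    with mismatch, N-content and uniqueness filters; tag-count
    normalization by distribution matching; efficiency-corrected qPCR
    quantification (window-of-linearity efficiency estimation, qBase-style
    relative quantities, reference-gene normalization); ChIP-qPCR
    percent-input and enrichment scoring with a two-criterion positivity
    rule; bivalency (H3K4me3/H3K27me3) classification from cross-species
    ortholog mark states; developmental fold-change-rate statistics; and
    an internally implemented Fisher exact test for contingency-based
    enrichment. A synthetic-data module generates every input the
    pipeline consumes with controllable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
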