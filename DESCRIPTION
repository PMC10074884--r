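Package: codonopt
Title: Context-Aware Codon Optimization with Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codon optimization for heterologous expression in Escherichia
    coli-like hosts. Implements a per-amino-acid bidirectional LSTM codon
    classifier trained on host coding sequences, with constrained decoding
    that guarantees synonymous output, alongside four frequency-based
    baseline optimizers (uniform random, background frequency, highest
    frequency, extended random choice). Includes the full surrounding
    machinery: FASTA and codon-usage-table input/output, a dataset curation
    pipeline (length filtering, greedy identity clustering, Codon Adaptation
    Index ranking, train/validation/test splitting), one-hot and
    physicochemical sequence encodings, an evaluation suite (CAI, GC-content,
    codon frequency distribution, repeat elements, cis-regulatory motifs,
    mutational rate), and a synthetic host-genome generator with controllable
    context-dependent codon usage for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
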