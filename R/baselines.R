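# Frequency-based comparison optimizers: uniform random choice (URC),
# background frequency choice (BFC), highest frequency choice (HFC), and
# extended random choice (ERC). All guarantee synonymous output.

aa_positions <- function(aa_seq, code) {
  res <- split_residues(aa_seq)
  unknown <- !res %in% c(names(code$aa_to_codons), STOP_SYMBOL)
  if (any(unknown)) {
    abort_alphabet(sprintf("unknown amino-acid symbol '%s' at position %d",
                           res[which(unknown)[1]], which(unknown)[1]))
  }
  if (any(res == STOP_SYMBOL & seq_along(res) < length(res))) {
    abort_alphabet("internal stop symbol in protein sequence")
  }
  res
}

# family_fraction of a family, with the degenerate-usage check.
family_dist <- function(aa, usage, code) {
  fam <- code$aa_to_codons[[aa]]
  p <- usage$family_fraction[fam]
  if (anyNA(p) || any(is.nan(p))) {
    abort_degenerate(sprintf("usage table has zero mass for family '%s'", aa))
  }
  p
}

# A position ending in "*" keeps TAA (the most common terminator) under
# random methods; callers optimizing a CDS re-attach the original stop.
sample_codons <- function(res, code, pick) {
  vapply(seq_along(res), function(i) {
    aa <- res[i]
    if (aa == STOP_SYMBOL) return("TAA")
    fam <- code$aa_to_codons[[aa]]
    if (length(fam) == 1L) fam else pick(aa, fam)
  }, character(1))
}

#' Uniform random choice optimizer
#'
#' Draws each position's codon uniformly from its synonymous family; the
#' most naive baseline.
#'
#' @param aa_seq Amino-acid sequence.
#' @param seed Integer seed; same seed, same output.
#' @param code A `genetic_code` object.
#' @return A CDS with `translate(result) == aa_seq`.
#' @export
urc_optimize <- function(aa_seq, seed = 1L, code = std_code()) {
  res <- aa_positions(aa_seq, code)
  withr::with_seed(seed, {
    paste(sample_codons(res, code, function(aa, fam) {
      fam[sample.int(length(fam), 1L)]
    }), collapse = "")
  })
}

#' Background frequency choice optimizer
#'
#' Samples each position's codon from its family's host usage distribution,
#' so the output's expected codon frequencies match the host background.
#'
#' @param aa_seq Amino-acid sequence.
#' @param usage A `codon_usage` object.
#' @param seed Integer seed.
#' @param code A `genetic_code` object.
#' @return A CDS with `translate(result) == aa_seq`.
#' @export
bfc_optimize <- function(aa_seq, usage = default_usage(), seed = 1L,
                         code = std_code()) {
  res <- aa_positions(aa_seq, code)
  withr::with_seed(seed, {
    paste(sample_codons(res, code, function(aa, fam) {
      p <- family_dist(aa, usage, code)
      fam[sample.int(length(fam), 1L, prob = p)]
    }), collapse = "")
  })
}

#' Highest frequency choice optimizer
#'
#' Deterministically replaces every codon with its family's most-used codon
#' in the host, the classic "CAI = 1.0" strategy: the output's CAI against
#' the same usage table is exactly 1. Within-family frequency ties break to
#' the lexicographically smaller codon.
#'
#' @inheritParams bfc_optimize
#' @return A CDS with `translate(result) == aa_seq` and CAI 1.0 under
#'   `usage`.
#' @export
hfc_optimize <- function(aa_seq, usage = default_usage(), code = std_code()) {
  res <- aa_positions(aa_seq, code)
  paste(sample_codons(res, code, function(aa, fam) {
    p <- family_dist(aa, usage, code)
    fam[which.max(p)]   # families are lexicographically sorted: ties -> first
  }), collapse = "")
}

#' Extended random choice optimizer
#'
#' Generates `k` uniform-random candidate sequences and returns the one with
#' the highest CAI against the host table (ties keep the first generated):
#' a sampled stand-in for exhaustive single-metric search.
#'
#' @inheritParams bfc_optimize
#' @param k Number of candidates (default 10000).
#' @return A CDS with `translate(result) == aa_seq`.
#' @export
erc_optimize <- function(aa_seq, usage = default_usage(), k = 10000L,
                         seed = 1L, code = std_code()) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L) {
    abort_config("k must be a positive integer")
  }
  k <- as.integer(k)
  res <- aa_positions(aa_seq, code)
  weights <- relative_adaptiveness(usage, code = code)
  scorable <- any(family_sizes(code)[res[res != STOP_SYMBOL]] > 1L)
  withr::with_seed(seed, {
    best <- NULL
    best_cai <- -Inf
    for (i in seq_len(k)) {
      cand <- paste(sample_codons(res, code, function(aa, fam) {
        fam[sample.int(length(fam), 1L)]
      }), collapse = "")
      score <- if (scorable) cai(cand, weights, code) else 1
      if (score > best_cai) {
        best <- cand
        best_cai <- score
      }
      if (!scorable) break   # all candidates identical
    }
    best
  })
}
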