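# Evaluation suite: CAI, GC-content, codon frequency distribution, repeat
# elements, cis-regulatory motifs, mutational rate, degeneracy.

#' Relative adaptiveness weights from a usage table
#'
#' Sharp-Li relative adaptiveness: within every synonymous family each
#' codon's weight is its family fraction divided by the family's maximal
#' fraction, so the most-used codon of each family has w = 1. Codons with
#' zero observed usage in a non-degenerate family are floored at w = 1e-4
#' rather than zero so the geometric mean stays finite. Families with no
#' observed usage at all get `NA` weights; scoring such a family raises a
#' degenerate-usage error at the point of use.
#'
#' @param usage A `codon_usage` object.
#' @param floor Lower floor for zero-usage codons (default 1e-4).
#' @param code A `genetic_code` object.
#' @return Object of class `adaptiveness_weights`: named numeric `w` over
#'   the sense codons.
#' @export
relative_adaptiveness <- function(usage, floor = 1e-4, code = std_code()) {
  ff <- usage$family_fraction
  w <- ff
  for (fam in code$aa_to_codons) {
    m <- suppressWarnings(max(ff[fam]))
    if (is.nan(m) || m <= 0) {
      w[fam] <- NA_real_
    } else {
      w[fam] <- pmax(ff[fam] / m, floor)
    }
  }
  structure(list(w = w, floor = floor), class = "adaptiveness_weights")
}

# Per-codon w for a vector of codons, erroring on degenerate families.
codon_weights <- function(codons, weights) {
  w <- weights$w[codons]
  if (anyNA(w)) {
    abort_degenerate(sprintf(
      "usage table has no observations for the family of codon '%s'",
      codons[which(is.na(w))[1]]))
  }
  unname(w)
}

#' Codon Adaptation Index
#'
#' Geometric mean of the relative adaptiveness w over a gene's scorable
#' codons. Stop codons and single-codon families (ATG, TGG under the
#' standard code) carry no information about synonymous choice and are
#' excluded from the mean, following the Sharp-Li convention.
#'
#' @param nt_seq A valid CDS (terminal stop allowed, ignored).
#' @param weights An `adaptiveness_weights` object.
#' @param code A `genetic_code` object.
#' @return CAI in (0, 1].
#' @export
cai <- function(nt_seq, weights, code = std_code()) {
  nt_seq <- assert_cds(nt_seq, code = code)
  codons <- split_codons(strip_terminal_stop(nt_seq, code))
  sizes <- family_sizes(code)
  keep <- sizes[code$codon_to_aa[codons]] > 1L
  scorable <- codons[keep]
  if (length(scorable) == 0L) {
    abort_undefined("no scorable codons (only stops or single-codon families)")
  }
  exp(mean(log(codon_weights(scorable, weights))))
}

#' GC-content of a sequence
#'
#' @param nt_seq Non-empty DNA string.
#' @return Percentage of G/C bases, 0..100.
#' @export
gc_content <- function(nt_seq) {
  nt_seq <- normalize_dna(nt_seq)
  n <- nchar(nt_seq)
  if (n == 0L) abort_undefined("GC-content of an empty sequence is undefined")
  100 * (n - nchar(gsub("[GC]", "", nt_seq))) / n
}

#' Codon frequency distribution (rare-codon percentage)
#'
#' Percentage of a gene's sense codons whose relative adaptiveness in the
#' host falls strictly below a threshold (default 0.30, the conventional
#' rare-codon cutoff). Lower is better; 0 means no rare codons.
#'
#' @param nt_seq A valid CDS (terminal stop allowed, ignored).
#' @param weights An `adaptiveness_weights` object.
#' @param threshold Rare-codon cutoff on w (strict `<`).
#' @param code A `genetic_code` object.
#' @return Percentage in 0..100.
#' @export
cfd <- function(nt_seq, weights, threshold = 0.30, code = std_code()) {
  nt_seq <- assert_cds(nt_seq, code = code)
  codons <- split_codons(strip_terminal_stop(nt_seq, code))
  if (length(codons) == 0L) abort_undefined("empty CDS")
  w <- codon_weights(codons, weights)
  100 * sum(w < threshold) / length(codons)
}

#' Count negative repeat elements
#'
#' Counts the distinct maximal repeated substrings of length at least
#' `min_len` on the direct strand: substrings occurring two or more times
#' (occurrences may overlap) that are not contained in any longer repeated
#' substring. Long exact repeats complicate synthesis and can trigger
#' recombination, hence "negative".
#'
#' @param nt_seq DNA string.
#' @param min_len Minimum repeat length (default 10).
#' @return Integer count.
#' @export
negative_repeats <- function(nt_seq, min_len = 10L) {
  nt_seq <- normalize_dna(nt_seq)
  n <- nchar(nt_seq)
  if (n < min_len + 1L) return(0L)
  # repeated-substring lengths are down-closed (a length-(L+1) repeat contains
  # a length-L repeat), so scan upward and stop at the first empty level; a
  # length-L repeat is maximal iff no length-(L+1) repeat contains it
  repeated_at <- function(L) {
    starts <- seq_len(n - L + 1L)
    subs <- substring(nt_seq, starts, starts + L - 1L)
    tab <- table(subs)
    names(tab)[tab >= 2L]
  }
  levels <- list()
  L <- min_len
  while (L <= n - 1L) {
    r <- repeated_at(L)
    if (length(r) == 0L) break
    levels[[length(levels) + 1L]] <- r
    L <- L + 1L
  }
  count <- 0L
  for (k in seq_along(levels)) {
    nxt <- if (k < length(levels)) levels[[k + 1L]] else character(0)
    maximal <- vapply(levels[[k]], function(s) {
      !any(vapply(nxt, function(t) grepl(s, t, fixed = TRUE), logical(1)))
    }, logical(1))
    count <- count + sum(maximal)
  }
  count
}

#' Default negative cis-regulatory motif set
#'
#' Internal ribosome-entry and promoter-like motifs counted as "negative"
#' inside a coding region: Shine-Dalgarno cores `AGGAGG` and `GGAGG`, the
#' sigma-70 minus-10 box `TATAAT`, the chi recombination site `GCTGGTGG`,
#' and A/T homopolymer runs of length 8.
#'
#' @return Named character vector of IUPAC DNA motifs.
#' @export
default_cis_motifs <- function() {
  c(sd_aggagg = "AGGAGG", sd_ggagg = "GGAGG", minus10 = "TATAAT",
    chi = "GCTGGTGG", polyA8 = "AAAAAAAA", polyT8 = "TTTTTTTT")
}

#' Count negative cis-regulatory elements
#'
#' Total number of motif matches over both strands (forward and reverse
#' complement); overlapping matches are all counted. Motifs may use IUPAC
#' degeneracy codes.
#'
#' @param nt_seq DNA string.
#' @param motifs Character vector of motifs (default [default_cis_motifs()]).
#' @return Integer count.
#' @export
negative_cis_elements <- function(nt_seq, motifs = default_cis_motifs()) {
  if (length(motifs) == 0L) return(0L)
  if (any(grepl("[^ACGTRYSWKMBDHVN]", toupper(motifs)))) {
    abort_config("motifs must be IUPAC DNA patterns")
  }
  subject <- Biostrings::DNAString(normalize_dna(nt_seq))
  rc <- Biostrings::reverseComplement(subject)
  total <- 0L
  for (m in toupper(motifs)) {
    pat <- Biostrings::DNAString(m)
    total <- total +
      Biostrings::countPattern(pat, subject, fixed = FALSE) +
      Biostrings::countPattern(pat, rc, fixed = FALSE)
  }
  total
}

#' Mutational rate of an optimized sequence
#'
#' Back-translates an optimizer's output and reports the percentage of
#' amino-acid positions that differ from the reference protein. Constrained
#' decoding guarantees 0; unconstrained decoding can be non-zero.
#'
#' @param reference_aa Reference amino-acid sequence.
#' @param optimized_nt Optimized CDS (terminal stop allowed, ignored).
#' @param code A `genetic_code` object.
#' @return Percentage in 0..100.
#' @export
mutational_rate <- function(reference_aa, optimized_nt, code = std_code()) {
  opt_aa <- translate(strip_terminal_stop(optimized_nt, code), code)
  if (nchar(opt_aa) != nchar(reference_aa)) {
    abort_data(sprintf("length mismatch: %d aa reference vs %d aa optimized",
                       nchar(reference_aa), nchar(opt_aa)))
  }
  if (nchar(reference_aa) == 0L) return(0)
  a <- split_residues(reference_aa)
  b <- split_residues(opt_aa)
  100 * sum(a != b) / length(a)
}

#' Mean codon degeneracy of a protein
#'
#' Mean synonymous-family size across the residues of a protein: the average
#' number of codon choices available per position.
#'
#' @param aa_seq Amino-acid string (standard residues).
#' @param code A `genetic_code` object.
#' @return Mean family size.
#' @export
mean_degeneracy <- function(aa_seq, code = std_code()) {
  res <- split_residues(aa_seq)
  if (length(res) == 0L) abort_undefined("empty protein")
  sizes <- family_sizes(code)[res]
  if (anyNA(sizes)) {
    abort_alphabet(sprintf("unknown amino-acid symbol '%s'",
                           res[which(is.na(sizes))[1]]))
  }
  mean(sizes)
}
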