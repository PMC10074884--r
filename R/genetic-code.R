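#' @useDynLib codonopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# All 64 codons in lexicographic order (A < C < G < T). This order fixes the
# label space of the classifier: label i <-> CODONS[i].
CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
CODONS <- sort(CODONS)

STOP_SYMBOL <- "*"

#' Build a genetic-code table
#'
#' Returns a data-driven genetic code object: the forward codon-to-amino-acid
#' map, its inverse partition into synonymous families, and the stop codons.
#' The standard code (NCBI translation table 1) is the built-in default;
#' alternate tables can be supplied as a named character vector in the same
#' shape as [Biostrings::GENETIC_CODE].
#'
#' @param table Named character vector mapping all 64 codons to one-letter
#'   amino-acid symbols (`"*"` for stop). Defaults to the standard code.
#' @return An object of class `genetic_code` with elements `codon_to_aa`
#'   (named character, lexicographic codon order), `aa_to_codons` (named list
#'   of lexicographically sorted synonymous families), and `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' gc$aa_to_codons$L   # the six leucine codons
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    table <- Biostrings::GENETIC_CODE
  }
  codons <- toupper(chartr("U", "T", names(table)))
  if (length(table) != 64L || anyDuplicated(codons) ||
      !setequal(codons, CODONS)) {
    abort_config("genetic-code table must map exactly the 64 codons")
  }
  codon_to_aa <- stats::setNames(unname(as.character(table)), codons)[CODONS]
  stops <- names(codon_to_aa)[codon_to_aa == STOP_SYMBOL]
  sense <- codon_to_aa[codon_to_aa != STOP_SYMBOL]
  aa_to_codons <- split(names(sense), sense)
  aa_to_codons <- lapply(aa_to_codons, sort)
  structure(
    list(codon_to_aa = codon_to_aa,
         aa_to_codons = aa_to_codons,
         stop_codons = stops),
    class = "genetic_code"
  )
}

# Cached standard code; almost every function takes `code = std_code()`.
.codonopt_cache <- new.env(parent = emptyenv())

std_code <- function() {
  if (is.null(.codonopt_cache$std)) .codonopt_cache$std <- genetic_code()
  .codonopt_cache$std
}

#' Sense codons of a genetic code
#'
#' @param code A `genetic_code` object.
#' @return Character vector of the 61 sense codons, lexicographic order.
#' @export
sense_codons <- function(code = std_code()) {
  setdiff(CODONS, code$stop_codons)
}

# Uppercase, RNA->DNA. Shared by every entry point that accepts sequence text.
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

split_codons <- function(nt_seq) {
  n <- nchar(nt_seq)
  if (n == 0L) return(character(0))
  substring(nt_seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Translates a DNA coding sequence to its amino-acid sequence under the
#' given genetic code. Stop codons render as `"*"`. Input is normalized
#' (case, U to T) before translation.
#'
#' @param nt_seq DNA string; length must be divisible by 3, alphabet ACGT.
#' @param code A `genetic_code` object.
#' @return Amino-acid string, one symbol per codon.
#' @examples
#' translate("ATGAAA")  # "MK"
#' @export
translate <- function(nt_seq, code = std_code()) {
  nt_seq <- normalize_dna(nt_seq)
  if (nchar(nt_seq) %% 3L != 0L) {
    abort_invalid_cds(sprintf("sequence length %d is not divisible by 3",
                              nchar(nt_seq)))
  }
  if (grepl("[^ACGT]", nt_seq)) {
    bad <- regmatches(nt_seq, regexpr("[^ACGT]", nt_seq))
    abort_alphabet(sprintf("non-ACGT character '%s' in coding sequence", bad))
  }
  if (nchar(nt_seq) == 0L) return("")
  paste(code$codon_to_aa[split_codons(nt_seq)], collapse = "")
}

#' Synonymous codons of an amino acid
#'
#' @param aa One-letter amino-acid symbol (or `"*"` for stop).
#' @param code A `genetic_code` object.
#' @return Character vector of the synonymous family, lexicographic order.
#' @examples
#' synonymous_codons("M")  # "ATG"
#' synonymous_codons("L")  # six codons
#' @export
synonymous_codons <- function(aa, code = std_code()) {
  if (length(aa) != 1L || is.na(aa)) abort_alphabet("aa must be one symbol")
  if (aa == STOP_SYMBOL) return(sort(code$stop_codons))
  fam <- code$aa_to_codons[[aa]]
  if (is.null(fam)) {
    abort_alphabet(sprintf("unknown amino-acid symbol '%s'", aa))
  }
  fam
}

#' Validate a coding sequence
#'
#' Reporting operation: checks length, alphabet and internal stops and
#' returns all violations rather than raising. A terminal stop codon is
#' allowed (and common in extracted CDS).
#'
#' @param nt_seq DNA string.
#' @param code A `genetic_code` object.
#' @return List of class `cds_validation`: `ok` (logical), `bad_length`,
#'   `bad_alphabet` (character positions of offending letters),
#'   `internal_stop` (codon indices, 1-based).
#' @export
validate_cds <- function(nt_seq, code = std_code()) {
  nt_seq <- normalize_dna(nt_seq)
  n <- nchar(nt_seq)
  bad_length <- n %% 3L != 0L
  chars <- strsplit(nt_seq, "")[[1]]
  bad_alphabet <- which(!chars %in% c("A", "C", "G", "T"))
  internal_stop <- integer(0)
  if (!bad_length && length(bad_alphabet) == 0L && n > 0L) {
    codons <- split_codons(nt_seq)
    stops <- which(codons %in% code$stop_codons)
    internal_stop <- stops[stops < length(codons)]
  }
  structure(
    list(ok = !bad_length && length(bad_alphabet) == 0L &&
           length(internal_stop) == 0L,
         bad_length = bad_length,
         bad_alphabet = bad_alphabet,
         internal_stop = internal_stop),
    class = "cds_validation"
  )
}

# Raise a classed error unless nt_seq is a clean CDS.
assert_cds <- function(nt_seq, what = "sequence", code = std_code()) {
  v <- validate_cds(nt_seq, code)
  if (!v$ok) {
    msgs <- c(
      if (v$bad_length) "length not divisible by 3",
      if (length(v$bad_alphabet)) sprintf("non-ACGT characters at %s",
                                          paste(v$bad_alphabet, collapse = ",")),
      if (length(v$internal_stop)) sprintf("internal stop at codon %s",
                                           paste(v$internal_stop, collapse = ","))
    )
    if (v$bad_length || length(v$bad_alphabet)) {
      abort_invalid_cds(sprintf("%s is not a valid CDS: %s", what,
                                paste(msgs, collapse = "; ")))
    }
    abort_invalid_cds(sprintf("%s has internal stop codons: %s", what,
                              paste(msgs, collapse = "; ")))
  }
  invisible(normalize_dna(nt_seq))
}

# Strip one terminal stop codon if present; returns the coding part.
strip_terminal_stop <- function(nt_seq, code = std_code()) {
  nt_seq <- normalize_dna(nt_seq)
  n <- nchar(nt_seq)
  if (n >= 3L && substring(nt_seq, n - 2L, n) %in% code$stop_codons) {
    return(substring(nt_seq, 1L, n - 3L))
  }
  nt_seq
}

# Synonymous family sizes per amino acid (named integer over the 20 aa).
family_sizes <- function(code = std_code()) {
  vapply(code$aa_to_codons, length, integer(1))
}
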