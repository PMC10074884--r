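#' Construct a codon-usage table
#'
#' A codon-usage table records, for every sense codon of the host, its raw
#' count (or weight), its frequency among all sense codons, and its fraction
#' within its synonymous family. It is the source of the relative
#' adaptiveness weights behind CAI and of the sampling distributions of the
#' frequency-based optimizers.
#'
#' @param counts Named non-negative numeric vector over (a subset of) the 61
#'   sense codons; missing codons are filled with zero.
#' @param code A `genetic_code` object.
#' @return Object of class `codon_usage`: `counts`, `freq` (sums to 1 over
#'   sense codons; all-`NaN` with `undefined = TRUE` when the total is zero)
#'   and `family_fraction` (sums to 1 within each family; `NaN` within
#'   all-zero families, listed in `degenerate_families`).
#' @export
codon_usage <- function(counts, code = std_code()) {
  sense <- sense_codons(code)
  nm <- normalize_dna(names(counts))
  if (is.null(names(counts)) || anyNA(nm)) abort_parse("counts must be named by codon")
  bad <- setdiff(nm, CODONS)
  if (length(bad)) abort_parse(sprintf("not a codon: '%s'", bad[1]))
  if (anyDuplicated(nm)) {
    abort_parse(sprintf("duplicate codon '%s'", nm[anyDuplicated(nm)]))
  }
  if (any(counts < 0)) abort_parse("codon counts must be non-negative")
  full <- stats::setNames(numeric(length(sense)), sense)
  keep <- intersect(nm, sense)
  full[keep] <- as.numeric(counts[match(keep, nm)])
  total <- sum(full)
  freq <- if (total > 0) full / total else full * NaN
  fam_frac <- full
  degenerate <- character(0)
  for (aa in names(code$aa_to_codons)) {
    fam <- code$aa_to_codons[[aa]]
    s <- sum(full[fam])
    if (s > 0) {
      fam_frac[fam] <- full[fam] / s
    } else {
      fam_frac[fam] <- NaN
      degenerate <- c(degenerate, aa)
    }
  }
  structure(
    list(counts = full, freq = freq, family_fraction = fam_frac,
         undefined = total <= 0, degenerate_families = degenerate),
    class = "codon_usage"
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d sense codons, total weight %.6g\n",
              length(x$counts), sum(x$counts)))
  if (length(x$degenerate_families)) {
    cat("  all-zero families:", paste(x$degenerate_families, collapse = " "), "\n")
  }
  invisible(x)
}

#' Tally codon usage from coding sequences
#'
#' Counts codons over a collection of valid CDS records, excluding stop
#' codons, and derives frequencies. Additive: the counts of a union of
#' collections equal the sum of the parts' counts.
#'
#' @param records A `gene_records` tibble whose `nt` column holds valid CDS.
#' @param code A `genetic_code` object.
#' @return A `codon_usage` object.
#' @export
usage_from_sequences <- function(records, code = std_code()) {
  sense <- sense_codons(code)
  if (nrow(records) == 0L) {
    return(codon_usage(stats::setNames(numeric(length(sense)), sense), code))
  }
  if (anyNA(records$nt)) abort_data("all records need an nt sequence")
  for (i in seq_len(nrow(records))) {
    assert_cds(records$nt[i], sprintf("record '%s'", records$id[i]), code)
  }
  dna <- Biostrings::DNAStringSet(records$nt)
  tab <- Biostrings::oligonucleotideFrequency(dna, width = 3L, step = 3L)
  counts <- colSums(tab)
  codon_usage(counts[intersect(names(counts), sense)], code)
}

#' Read a two-column codon-usage table
#'
#' Parses simple whitespace- or comma-delimited `codon value` lines
#' (Kazusa-style). Values are auto-detected as per-thousand frequencies when
#' they sum to approximately 1000, otherwise treated as raw counts; either
#' way frequencies are derived by normalization. Lines starting with `#` are
#' comments. Stop-codon lines are ignored; sense codons missing from the file
#' are zero-filled with a warning.
#'
#' @param path Path to the table.
#' @param code A `genetic_code` object.
#' @return A `codon_usage` object.
#' @export
read_usage_table <- function(path, code = std_code()) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort_parse(sprintf("empty usage table: %s", path))
  parts <- strsplit(lines, "[,[:space:]]+")
  if (any(lengths(parts) != 2L)) {
    abort_parse(sprintf("line %d of %s is not 'codon value'",
                        which(lengths(parts) != 2L)[1], path))
  }
  codons <- normalize_dna(vapply(parts, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(vals)) abort_parse(sprintf("non-numeric value on line %d of %s",
                                       which(is.na(vals))[1], path))
  if (any(!codons %in% CODONS)) {
    abort_parse(sprintf("not a codon: '%s'", codons[!codons %in% CODONS][1]))
  }
  if (anyDuplicated(codons)) {
    abort_parse(sprintf("duplicate codon '%s' in %s",
                        codons[anyDuplicated(codons)], path))
  }
  keep <- !codons %in% code$stop_codons
  codons <- codons[keep]; vals <- vals[keep]
  missing <- setdiff(sense_codons(code), codons)
  if (length(missing)) {
    warning(sprintf("%d sense codons missing from %s; filled with zero",
                    length(missing), path), call. = FALSE)
  }
  codon_usage(stats::setNames(vals, codons), code)
}

#' Write a codon-usage table
#'
#' Two-column `codon count` text, one sense codon per line, lexicographic
#' order. Round-trips with [read_usage_table()].
#'
#' @param usage A `codon_usage` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(usage, path) {
  writeLines(sprintf("%s %.10g", names(usage$counts), usage$counts), path)
  invisible(path)
}

#' Bundled default host usage table
#'
#' Loads the package's bundled host codon-usage table, a synthetic
#' approximation of E. coli K-12 codon usage (per-thousand scale) shipped so
#' the optimizers work out of the box. It is a stand-in, not a measured
#' reference table: supply your own host table (e.g. tallied from host CDS
#' with [usage_from_sequences()] or loaded with [read_usage_table()]) for
#' real design work.
#'
#' @return A `codon_usage` object.
#' @export
default_usage <- function() {
  if (is.null(.codonopt_cache$default_usage)) {
    path <- system.file("extdata", "ecoli_like_usage_synthetic.tsv",
                        package = "codonopt", mustWork = TRUE)
    .codonopt_cache$default_usage <- read_usage_table(path)
  }
  .codonopt_cache$default_usage
}
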