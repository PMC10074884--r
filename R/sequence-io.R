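#' Construct a gene-record table
#'
#' The package's unit of sequence data is a tibble with one row per gene and
#' columns `id`, `description`, `nt` (CDS, `NA` if absent) and `aa`
#' (amino-acid sequence, `NA` if absent). When both `nt` and `aa` are given
#' they must agree under translation (ignoring a terminal stop).
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param nt Optional character vector of coding sequences.
#' @param aa Optional character vector of amino-acid sequences.
#' @param description Optional character vector of free-text descriptions.
#' @return A tibble of class `gene_records`.
#' @export
gene_records <- function(id, nt = NULL, aa = NULL, description = "") {
  n <- length(id)
  if (n && (anyNA(id) || any(!nzchar(id)))) {
    abort_data("record ids must be non-empty")
  }
  if (anyDuplicated(id)) {
    abort_data(sprintf("duplicate record id '%s'", id[anyDuplicated(id)]))
  }
  nt <- if (is.null(nt)) rep(NA_character_, n) else normalize_dna(nt)
  aa <- if (is.null(aa)) rep(NA_character_, n) else toupper(aa)
  both <- which(!is.na(nt) & !is.na(aa))
  for (i in both) {
    tr <- translate(strip_terminal_stop(nt[i]))
    if (tr != aa[i]) {
      abort_data(sprintf("record '%s': nt does not translate to aa", id[i]))
    }
  }
  out <- tibble::tibble(id = as.character(id),
                        description = rep_len(as.character(description), n),
                        nt = nt, aa = aa)
  class(out) <- c("gene_records", class(out))
  out
}

# Amino-acid sequence per record, deriving from nt where aa is absent.
record_aa <- function(records) {
  aa <- records$aa
  need <- which(is.na(aa))
  for (i in need) {
    if (is.na(records$nt[i])) {
      abort_data(sprintf("record '%s' has neither nt nor aa", records$id[i]))
    }
    aa[i] <- translate(strip_terminal_stop(records$nt[i]))
  }
  aa
}

#' Read a FASTA file into gene records
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @param alphabet `"dna"` for coding sequences or `"protein"`.
#' @return A `gene_records` tibble, input order preserved; the sequence goes
#'   into `nt` or `aa` according to `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_parse(
                    sprintf("cannot parse FASTA '%s': %s", path,
                            conditionMessage(e))))
  if (length(set) == 0L) return(gene_records(character(0)))
  heads <- names(set)
  ids <- sub("\\s.*$", "", heads)
  desc <- sub("^\\S+\\s*", "", heads)
  seqs <- unname(toupper(as.character(set)))
  if (any(!nzchar(seqs))) {
    abort_parse(sprintf("empty sequence for record '%s' in %s",
                        ids[which(!nzchar(seqs))[1]], path))
  }
  if (alphabet == "dna") {
    seqs <- normalize_dna(seqs)
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      abort_alphabet(sprintf("record '%s' contains non-ACGT characters",
                             ids[which(bad)[1]]))
    }
    gene_records(ids, nt = seqs, description = desc)
  } else {
    allowed <- "[^ACDEFGHIKLMNPQRSTVWYUOBZX*]"
    bad <- grepl(allowed, seqs)
    if (any(bad)) {
      abort_alphabet(sprintf("record '%s' contains non-amino-acid characters",
                             ids[which(bad)[1]]))
    }
    gene_records(ids, aa = seqs, description = desc)
  }
}

#' Write gene records to FASTA
#'
#' Writes the `nt` column if present for all records, otherwise the `aa`
#' column. Round-trips with [read_fasta()].
#'
#' @param records A `gene_records` tibble.
#' @param path Output path.
#' @param line_width Sequence line width (default 60).
#' @param what `"auto"`, `"nt"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L,
                        what = c("auto", "nt", "aa")) {
  what <- match.arg(what)
  if (what == "auto") what <- if (all(!is.na(records$nt))) "nt" else "aa"
  seqs <- records[[what]]
  if (anyNA(seqs)) {
    abort_data(sprintf("record '%s' has no %s sequence",
                       records$id[which(is.na(seqs))[1]], what))
  }
  heads <- ifelse(nzchar(records$description),
                  paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(stats::setNames(seqs, heads))
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}
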