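# --- residue alphabet -------------------------------------------------------

#' The 26-symbol residue alphabet
#'
#' Ordered alphabet used by the one-hot encoding: the 20 standard amino
#' acids plus selenocysteine (U), pyrrolysine (O), the ambiguity codes B, Z,
#' X and the stop symbol `*`. Alanine occupies feature position 1; the
#' remaining letters follow alphabetically with the stop symbol last. The
#' alphabet is configuration data: any 26-symbol bijection with Alanine
#' first is accepted by the encoders.
#'
#' @return Object of class `alphabet_spec`: `symbols` (length 26) and
#'   `index` (named integer map symbol -> feature position).
#' @export
alphabet_spec <- function() {
  symbols <- c("A", setdiff(LETTERS[LETTERS != "J"], "A"), "*")
  stopifnot(length(symbols) == 26L, symbols[1] == "A")
  structure(
    list(symbols = symbols,
         index = stats::setNames(seq_along(symbols), symbols)),
    class = "alphabet_spec"
  )
}

split_residues <- function(aa_seq) {
  if (nchar(aa_seq) == 0L) return(character(0))
  strsplit(toupper(aa_seq), "")[[1]]
}

#' One-hot encode an amino-acid sequence
#'
#' Each residue becomes a 26-long indicator vector: 1 at the residue's
#' alphabet position, 0 elsewhere. Alanine maps to the first feature.
#'
#' @param aa_seq Amino-acid string.
#' @param alphabet An `alphabet_spec`.
#' @return Numeric matrix T x 26, one row per residue.
#' @export
one_hot_encode <- function(aa_seq, alphabet = alphabet_spec()) {
  res <- split_residues(aa_seq)
  idx <- alphabet$index[res]
  if (anyNA(idx)) {
    abort_alphabet(sprintf("unknown symbol '%s' at position %d",
                           res[which(is.na(idx))[1]], which(is.na(idx))[1]))
  }
  m <- matrix(0, nrow = length(res), ncol = length(alphabet$symbols))
  if (length(res)) m[cbind(seq_along(idx), idx)] <- 1
  colnames(m) <- alphabet$symbols
  m
}

# 18 z-scored physicochemical descriptors per standard amino acid, frozen
# from published AAindex property scales (hydropathy KYTJ820101, hydrophilicity
# HOPT810101, polarity GRAR740102, volume GRAR740103, mol. weight-related
# FAUJ880103, pK/charge ZIMJ680104, FASG760101, accessibility CHOC760101,
# JANJ780101, secondary-structure propensities CHOP780201/02/03, flexibility
# BHAR880101, KARP850102, H-bonding FAUJ880109/111/112, transfer energy
# RADA880108). Columns standardized to mean 0, sd 1 across the 20 residues.
NLFT_TABLE <- rbind(
  A = c(0.7667, -0.1480, -0.0836, -1.2345, -1.4248, -0.0150, -1.5490, -1.2645, -0.7887, 1.4942, -0.5390, -0.6853, -0.8413, -0.5086, -0.8173, -0.4094, -0.3249, -0.2488),
  C = c(1.0010, -0.4077, -1.0500, -0.6757, -0.6871, -0.5519, -0.5103, -0.8068, -1.3003, -1.0673, 0.4385, -0.0858, -0.9739, -1.4322, -0.8173, -0.4094, -0.3249, 1.3681),
  D = c(-1.0077, 1.6699, 1.7376, -0.6990, -0.5066, -1.8407, -0.1231, -0.4635, 0.5754, 0.0356, -1.3264, 1.4400, 1.0149, 1.4336, 0.1442, -0.4094, 2.9240, -1.0914),
  E = c(-1.0077, 1.6699, 1.4774, -0.0239, 0.0093, -1.5863, 0.3314, 0.4520, 0.8915, 1.8144, -1.7880, -0.1131, 0.8461, 0.7137, 0.1442, -0.4094, 2.9240, -1.0573),
  F = c(1.1015, -1.1869, -1.1615, 1.1169, 1.0977, -0.3089, 0.9165, 0.9097, -0.8844, 0.4625, 0.9544, -0.9032, -1.3596, -0.9704, -0.8173, -0.4094, -0.3249, 1.2657),
  G = c(0.0301, 0.1117, 0.2509, -1.8864, -1.9406, -0.0319, -2.0032, -2.1799, -0.9260, -1.5298, -0.7562, 1.5490, 1.4126, 0.7952, -0.8173, -0.4094, -0.3249, -0.6473),
  H = c(-0.9073, -0.1480, 0.7712, 0.2788, 0.4632, 0.8837, 0.5916, 0.5664, 0.1637, 0.0000, -0.4304, -0.1131, -1.2511, -0.4272, 0.1442, 2.3202, -0.3249, 0.3775),
  I = c(1.6706, -0.8233, -1.1615, 0.6280, 0.1228, -0.0037, -0.1857, 0.1087, -0.9967, 0.2846, 1.5518, -1.4209, 0.4243, -1.2421, -0.8173, -0.4094, -0.3249, 1.3112),
  K = c(-1.1416, 1.6699, 1.1057, 0.8143, 0.5200, 2.0990, 0.3009, 0.6809, 2.3387, 0.5692, -0.7834, 0.5409, 0.4725, 1.3385, 1.1058, 2.3202, -0.3249, -1.5241),
  L = c(1.4362, -0.8233, -1.2730, 0.6280, 0.1228, -0.0263, -0.1857, -0.0057, -0.7970, 0.7471, 0.7372, -1.3392, -0.7449, -0.3049, -0.8173, -0.4094, -0.3249, 1.1973),
  M = c(0.8001, -0.5636, -0.9757, 0.4883, 0.3446, -0.1619, 0.3988, 0.3376, -0.5517, 1.6009, 0.0584, -1.0667, -1.5886, -1.6495, -0.8173, -0.4094, -0.3249, 1.2657),
  N = c(-1.0077, 0.2156, 1.2172, -0.6525, -0.4189, -0.3485, -0.1549, -0.2346, 0.5546, -1.1740, -0.3761, 1.2765, 0.4363, 0.3063, 1.1058, -0.4094, -0.3249, -0.7271),
  P = c(-0.3716, 0.1117, -0.1208, -1.1996, -0.5375, 0.1546, -0.7053, -0.5779, 0.1969, -1.5298, -1.2993, 1.5490, 0.9908, 1.3793, -0.8173, -0.4094, -0.3249, -0.1805),
  Q = c(-1.0077, 0.2156, 0.8084, 0.0227, 0.0970, -0.2128, 0.2997, 0.2231, 0.9122, 0.3913, 0.1941, -0.0858, 0.7979, 0.5643, 1.1058, -0.4094, -0.3249, -1.0117),
  R = c(-1.3425, 1.6699, 0.8084, 0.9307, 1.2215, 2.6755, 1.2084, 1.2530, 1.9936, -0.0712, -0.2675, 0.0504, 1.2318, 0.6051, 3.0289, 2.3202, -0.3249, -1.1370),
  S = c(-0.1038, 0.2675, 0.3252, -1.2112, -1.1153, -0.1959, -1.0306, -1.2645, -0.1982, -0.8182, -0.7562, 1.1948, 0.9666, 0.8767, 0.1442, -0.4094, -0.3249, -0.7498),
  T = c(-0.0703, -0.0961, 0.1022, -0.5361, -0.5994, -0.2072, -0.5761, -0.6923, -0.0734, -0.6048, 0.4385, -0.0313, 0.2073, 0.9175, 0.1442, -0.4094, -0.3249, -0.4879),
  V = c(1.5702, -0.6674, -0.9013, -0.0006, -0.3931, -0.0376, -0.6399, -0.3490, -0.9592, 0.2135, 1.8233, -1.0940, -0.4918, -0.7667, -0.8173, -0.4094, -0.3249, 1.0607),
  W = c(-0.1373, -1.6543, -1.0872, 2.0016, 2.2274, -0.0772, 2.1817, 1.9396, -0.5018, 0.2846, 0.9273, -1.0667, -1.4681, -0.9025, 0.1442, -0.4094, -0.3249, 0.8216),
  Y = c(-0.2712, -1.0830, -0.7898, 1.2100, 1.3969, -0.2072, 1.4349, 1.3675, 0.3508, -1.1029, 1.1988, 0.4046, -0.0820, -0.7260, 0.1442, -0.4094, -0.3249, 0.1953)
)

#' Physicochemical (18-feature) residue encoding
#'
#' Encodes each standard amino acid as a deterministic 18-dimensional
#' real-valued descriptor built from z-scored published property scales
#' (hydropathy, polarity, volume, charge, accessibility, secondary-structure
#' propensity, flexibility, hydrogen bonding). An alternative to the one-hot
#' encoding for the classifier input.
#'
#' @param aa_seq Amino-acid string (20 standard residues only).
#' @return Numeric matrix T x 18.
#' @export
nlft_encode <- function(aa_seq) {
  res <- split_residues(aa_seq)
  idx <- match(res, rownames(NLFT_TABLE))
  if (anyNA(idx)) {
    abort_alphabet(sprintf("symbol '%s' at position %d has no descriptor",
                           res[which(is.na(idx))[1]], which(is.na(idx))[1]))
  }
  m <- NLFT_TABLE[idx, , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Dispatch helper used by the model code.
encode_features <- function(aa_seq, encoding = c("onehot", "nlft"),
                            alphabet = alphabet_spec()) {
  encoding <- match.arg(encoding)
  if (encoding == "onehot") one_hot_encode(aa_seq, alphabet)
  else nlft_encode(aa_seq)
}

# --- codon class labels -----------------------------------------------------

#' Codon class labels of a CDS
#'
#' Maps each codon of a valid CDS to its fixed lexicographic index in the
#' 64-codon label space (AAA = 1, ..., TTT = 64). These are the supervision
#' targets of the classifier; [decode_labels()] inverts the mapping exactly.
#'
#' @param nt_seq A valid CDS (terminal stop allowed and labelled).
#' @return Integer vector of labels in 1..64.
#' @examples
#' codon_labels("AAAAAC")  # c(1, 2)
#' @export
codon_labels <- function(nt_seq) {
  nt_seq <- assert_cds(nt_seq)
  match(split_codons(nt_seq), CODONS)
}

#' Decode codon class labels back to a CDS
#'
#' @param labels Integer vector in 1..64.
#' @return The nucleotide sequence (3 nt per label).
#' @export
decode_labels <- function(labels) {
  if (length(labels) == 0L) return("")
  if (any(labels < 1L | labels > 64L)) abort_data("labels must be in 1..64")
  paste(CODONS[labels], collapse = "")
}

#' Encode a gene for the classifier
#'
#' Bundles the per-position feature matrix of a record's amino-acid sequence
#' with, when a CDS is available, its per-position codon labels (the terminal
#' stop, if any, is stripped so that labels align with residues one-to-one).
#'
#' @param record One row of a `gene_records` tibble (or a list with `aa`/`nt`).
#' @param encoding `"onehot"` (26 features) or `"nlft"` (18 features).
#' @param alphabet An `alphabet_spec`.
#' @return Object of class `encoded_gene`: `features` (T x F), `labels`
#'   (length-T integer or `NULL`), `length` (T).
#' @export
encode_gene <- function(record, encoding = c("onehot", "nlft"),
                        alphabet = alphabet_spec()) {
  encoding <- match.arg(encoding)
  aa <- record$aa
  nt <- record$nt
  if (is.null(aa) || is.na(aa)) {
    if (is.null(nt) || is.na(nt)) abort_data("record has neither aa nor nt")
    aa <- translate(strip_terminal_stop(nt))
  }
  features <- encode_features(aa, encoding, alphabet)
  labels <- NULL
  if (!is.null(nt) && !is.na(nt)) {
    labels <- codon_labels(strip_terminal_stop(nt))
    if (length(labels) != nrow(features)) {
      abort_data("label/feature length mismatch")
    }
  }
  structure(list(features = features, labels = labels,
                 length = nrow(features)),
            class = "encoded_gene")
}
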