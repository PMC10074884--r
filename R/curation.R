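# Training-set curation pipeline: length filter -> greedy identity
# clustering -> CAI ranking/selection -> train/validation/test split.

#' Filter records by protein length
#'
#' Retains records whose protein is at least `min_aa_length` residues
#' (derived from the CDS where `aa` is absent); short genes are typically
#' hypothetical or specialized and are excluded from training.
#'
#' @param records A `gene_records` tibble.
#' @param min_aa_length Minimum length in amino acids (default 90).
#' @return The retained records, input order preserved.
#' @export
filter_by_length <- function(records, min_aa_length = 90L) {
  if (nrow(records) == 0L) return(records)
  len <- nchar(record_aa(records))
  records[len >= min_aa_length, , drop = FALSE]
}

# Best ungapped identity between two sequences over a set of candidate
# diagonals: matches at the best offset divided by the shorter length.
identity_at_offsets <- function(a, b, offsets) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  shorter <- min(la, lb)
  best <- 0L
  for (d in unique(offsets)) {
    # align a[i] with b[i + d]
    ia <- max(1L, 1L - d); ib <- ia + d
    n <- min(la - ia, lb - ib) + 1L
    if (n < 1L || n <= best) next
    idx <- seq_len(n)
    m <- sum(ca[ia + idx - 1L] == cb[ib + idx - 1L])
    if (m > best) best <- m
  }
  best / shorter
}

# Candidate diagonals anchored on shared k-mers (plus the zero diagonal).
kmer_offsets <- function(a, b, word_size) {
  la <- nchar(a); lb <- nchar(b)
  k <- min(word_size, la, lb)
  if (k < 1L) return(0L)
  starts_a <- seq_len(la - k + 1L)
  starts_b <- seq_len(lb - k + 1L)
  ka <- substring(a, starts_a, starts_a + k - 1L)
  kb <- substring(b, starts_b, starts_b + k - 1L)
  shared <- intersect(ka, kb)
  offs <- 0L
  for (w in shared) {
    pa <- which(ka == w)
    pb <- which(kb == w)
    offs <- c(offs, as.vector(outer(pb, pa, `-`)))
  }
  unique(offs)
}

seq_identity <- function(a, b, word_size = 8L) {
  identity_at_offsets(a, b, kmer_offsets(a, b, word_size))
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Greedy CD-HIT-style clustering of nucleotide sequences: sort by length
#' descending (stable), then each sequence joins the first existing cluster
#' whose representative it matches at more than `identity_threshold`
#' ungapped identity (best k-mer-anchored diagonal, matches divided by the
#' shorter length), otherwise founds a new cluster. Only representatives
#' are returned.
#'
#' @param records A `gene_records` tibble with `nt` sequences.
#' @param identity_threshold Identity above which sequences cluster
#'   (default 0.90; strict `>` comparison).
#' @param word_size Anchor k-mer length (default 8).
#' @return List: `representatives` (a `gene_records` tibble) and `clusters`
#'   (integer cluster id per input record, in input order).
#' @export
cluster_redundant <- function(records, identity_threshold = 0.90,
                              word_size = 8L) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    abort_config("identity_threshold must be in (0, 1]")
  }
  n <- nrow(records)
  clusters <- integer(n)
  if (n == 0L) return(list(representatives = records, clusters = clusters))
  if (anyNA(records$nt)) abort_data("clustering needs nt sequences")
  ord <- order(-nchar(records$nt))   # stable: ties keep input order
  rep_idx <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (j in seq_along(rep_idx)) {
      if (seq_identity(records$nt[i], records$nt[rep_idx[j]],
                       word_size) > identity_threshold) {
        clusters[i] <- j
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      clusters[i] <- length(rep_idx)
    }
  }
  list(representatives = records[sort(rep_idx), , drop = FALSE],
       clusters = clusters)
}

#' Rank records by CAI and keep the top N
#'
#' Computes CAI per record against the host usage table, sorts descending
#' (ties broken by longer CDS, then lexicographic id) and returns the first
#' `top_n` in rank order.
#'
#' @param records A `gene_records` tibble with `nt` sequences.
#' @param usage A `codon_usage` object.
#' @param top_n Number of records to keep (0..nrow).
#' @return The selected records with a `cai` column appended, best first.
#' @export
rank_and_select <- function(records, usage = default_usage(), top_n) {
  if (top_n > nrow(records) || top_n < 0L) {
    abort_config(sprintf("top_n = %d outside 0..%d", top_n, nrow(records)))
  }
  weights <- relative_adaptiveness(usage)
  score <- vapply(records$nt, function(s) cai(s, weights), numeric(1),
                  USE.NAMES = FALSE)
  ord <- order(-score, -nchar(records$nt), records$id)
  out <- records[ord, , drop = FALSE]
  out$cai <- score[ord]
  utils::head(out, top_n)
}

#' Split records into train/validation/test sets
#'
#' Shuffles with the given seed, then takes `round(f_val * N)` records for
#' validation, `round(f_test * N)` for test, and the remainder for training
#' (this rounding convention reproduces a 5,184/741/1,481 partition of
#' 7,406 at fractions 0.7/0.1/0.2). The partition is exact: disjoint and
#' exhaustive.
#'
#' @param records A `gene_records` tibble.
#' @param fractions Numeric triple (train, validation, test) summing to 1.
#' @param seed Integer shuffle seed.
#' @return List of `gene_records`: `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort_config("fractions must be three positives summing to 1")
  }
  n <- nrow(records)
  if (n == 0L) {
    return(list(train = records, validation = records, test = records))
  }
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 0L) abort_config("fractions leave no training data")
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = records[perm[seq_len(n_train)], , drop = FALSE],
       validation = records[perm[n_train + seq_len(n_val)], , drop = FALSE],
       test = records[perm[n_train + n_val + seq_len(n_test)], , drop = FALSE])
}

#' Run the full curation pipeline
#'
#' Length filter, redundancy clustering, CAI ranking/selection and
#' train/validation/test split in one call, with a per-record log.
#'
#' @param records A `gene_records` tibble with CDS.
#' @param usage A `codon_usage` object for CAI ranking.
#' @param min_aa_length Length floor in amino acids (default 90).
#' @param identity_threshold Clustering identity threshold (default 0.90).
#' @param top_n Number of top-CAI records to keep; capped at the number of
#'   cluster representatives.
#' @param fractions Split fractions (default 0.7/0.1/0.2).
#' @param seed Shuffle seed.
#' @return List: `train`, `validation`, `test` (`gene_records`), and `log`
#'   (tibble: id, length_aa, cai, cluster, partition).
#' @export
curate <- function(records, usage = default_usage(), min_aa_length = 90L,
                   identity_threshold = 0.90, top_n = NULL,
                   fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  kept <- filter_by_length(records, min_aa_length)
  clust <- cluster_redundant(kept, identity_threshold)
  reps <- clust$representatives
  if (is.null(top_n)) top_n <- nrow(reps)
  top_n <- min(top_n, nrow(reps))
  sel <- rank_and_select(reps, usage, top_n)
  parts <- split_dataset(sel, fractions, seed)
  partition <- stats::setNames(
    rep(c("train", "validation", "test"),
        vapply(parts, nrow, integer(1))),
    c(parts$train$id, parts$validation$id, parts$test$id))
  log <- tibble::tibble(
    id = records$id,
    length_aa = vapply(seq_len(nrow(records)), function(i) {
      nchar(record_aa(records[i, , drop = FALSE]))
    }, integer(1)),
    cai = sel$cai[match(records$id, sel$id)],
    cluster = clust$clusters[match(records$id, kept$id)],
    partition = unname(partition[records$id])
  )
  list(train = parts$train, validation = parts$validation,
       test = parts$test, log = log)
}
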