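# Independent brute-force oracles used to cross-check the package's
# algorithmic implementations, plus small fixture builders. These share no
# code with the implementations they verify.

# Ungapped identity maximized over ALL diagonals (not just k-mer anchored):
# matches at the best offset divided by the shorter length.
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  best <- 0L
  for (d in seq(-(la - 1L), lb - 1L)) {
    ia <- max(1L, 1L - d)
    ib <- ia + d
    n <- min(la - ia, lb - ib) + 1L
    if (n < 1L) next
    idx <- seq_len(n) - 1L
    m <- sum(ca[ia + idx] == cb[ib + idx])
    if (m > best) best <- m
  }
  best / min(la, lb)
}

# Same greedy clustering order as the implementation, but with exhaustive
# all-diagonal identities.
oracle_cluster <- function(nt, threshold) {
  ord <- order(-nchar(nt))
  clusters <- integer(length(nt))
  reps <- integer(0)
  for (i in ord) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (oracle_identity(nt[i], nt[reps[j]]) > threshold) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      clusters[i] <- length(reps)
    } else {
      clusters[i] <- hit
    }
  }
  list(clusters = clusters, representatives = sort(reps))
}

# Exhaustive repeated-substring tally: every substring of every length >=
# min_len, counted over all (overlapping) start positions; maximal = not a
# substring of any longer repeated substring.
oracle_repeats <- function(nt, min_len = 10L) {
  n <- nchar(nt)
  if (n < min_len + 1L) return(0L)
  by_len <- list()
  for (L in seq(min_len, n - 1L)) {
    starts <- seq_len(n - L + 1L)
    subs <- substring(nt, starts, starts + L - 1L)
    tab <- table(subs)
    r <- names(tab)[tab >= 2L]
    if (length(r) == 0L) {
      by_len[[as.character(L)]] <- character(0)
      next
    }
    by_len[[as.character(L)]] <- r
  }
  all_rep <- unlist(by_len, use.names = FALSE)
  if (length(all_rep) == 0L) return(0L)
  sum(vapply(all_rep, function(s) {
    longer <- all_rep[nchar(all_rep) > nchar(s)]
    !any(vapply(longer, function(t) grepl(s, t, fixed = TRUE), logical(1)))
  }, logical(1)))
}

# Exhaustive synonymous back-translation optimum: enumerate every codon
# combination of a short protein and return the maximal CAI.
oracle_best_cai <- function(aa_seq, weights) {
  res <- strsplit(aa_seq, "")[[1]]
  fams <- lapply(res, synonymous_codons)
  grid <- expand.grid(fams, stringsAsFactors = FALSE)
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    s <- paste(unlist(grid[r, ]), collapse = "")
    best <- max(best, cai(s, weights))
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(rownames(codonopt:::NLFT_TABLE), n, replace = TRUE),
        collapse = "")
}

random_usage <- function(seed) {
  withr::with_seed(seed, {
    codon_usage(stats::setNames(stats::runif(61, 0.05, 1), sense_codons()))
  })
}

# Random valid CDS of n codons (no stops).
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Memoized trained models so several test files can share one training run.
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

# Standard small training setup on a synthetic host; returns the model, the
# held-out records, the host, and the held-out codon-match accuracy.
train_on_host <- function(context_order, host_seed, seed,
                          encoding = "onehot", n_genes = 200L,
                          max_aa = 180L) {
  host <- make_host(seed = host_seed, context_order = context_order,
                    bias_strength = 0.6)
  genes <- sample_genes(host, n_genes, list(min_aa = 90L, max_aa = max_aa),
                        seed = seed)
  n_tr <- round(0.7 * n_genes)
  n_va <- round(0.1 * n_genes)
  tr <- genes[seq_len(n_tr), ]
  va <- genes[n_tr + seq_len(n_va), ]
  te <- genes[(n_tr + n_va + 1L):n_genes, ]
  model <- train_optimizer(tr, va, test_profile(seed = seed,
                                                encoding = encoding))
  list(model = model, test = te, host = host,
       accuracy = codonopt:::codon_match_accuracy(model, te))
}
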