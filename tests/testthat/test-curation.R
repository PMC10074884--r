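test_that("length filtering is a >= 90-residue boundary", {
  recs <- gene_records(c("short", "exact", "long"),
                       aa = c(strrep("A", 89), strrep("A", 90),
                              strrep("A", 120)))
  kept <- filter_by_length(recs, 90L)
  expect_identical(kept$id, c("exact", "long"))
  expect_identical(nrow(filter_by_length(gene_records(character(0)))), 0L)
  # length derivable from nt when aa is absent
  nt <- strrep("ATG", 90)
  expect_identical(filter_by_length(gene_records("x", nt = nt), 90L)$id, "x")
})

test_that("identical sequences collapse and dissimilar ones survive", {
  s <- random_cds(40)
  two <- gene_records(c("a", "b"), nt = c(s, s))
  res <- cluster_redundant(two, 0.90)
  expect_identical(nrow(res$representatives), 1L)
  expect_identical(res$clusters, c(1L, 1L))
  withr::with_seed(1, {
    u <- gene_records(c("a", "b"), nt = c(random_dna(120), random_dna(120)))
  })
  expect_identical(nrow(cluster_redundant(u, 0.90)$representatives), 2L)
  expect_error(cluster_redundant(two, 0), class = "codonopt_config_error")
})

test_that("greedy clustering matches the all-pairs brute-force oracle", {
  for (trial in 1:8) {
    withr::with_seed(100 + trial, {
      n_base <- sample(4:8, 1)
      seqs <- replicate(n_base, random_dna(sample(60:120, 1)))
      # plant near-duplicates: copy with a few point substitutions
      for (k in seq_len(sample(2:6, 1))) {
        src <- sample(seqs, 1)
        ch <- strsplit(src, "")[[1]]
        n_mut <- sample(0:3, 1)
        pos <- sample(length(ch), n_mut)
        ch[pos] <- sample(c("A", "C", "G", "T"), n_mut, replace = TRUE)
        seqs <- c(seqs, paste(ch, collapse = ""))
      }
      seqs <- sample(seqs)
    })
    recs <- gene_records(sprintf("s%02d", seq_along(seqs)), nt = seqs)
    got <- cluster_redundant(recs, 0.90)
    want <- oracle_cluster(seqs, 0.90)
    expect_identical(got$clusters, want$clusters)
    expect_identical(match(got$representatives$id, recs$id),
                     want$representatives)
  }
})

test_that("CAI ranking selects the top records in stable order", {
  u <- default_usage()
  w <- relative_adaptiveness(u)
  # construct three CDS with known CAI ordering
  lo <- hfc_optimize(strrep("LR", 20), u)       # cai = 1
  mid <- paste(rep(c("CTG", "CTA"), 20), collapse = "")
  recs <- gene_records(c("worst", "best", "middle"),
                       nt = c(strrep("CTA", 40), lo, mid))
  sel <- rank_and_select(recs, u, 2L)
  expect_identical(sel$id, c("best", "middle"))
  expect_true(all(diff(sel$cai) <= 0))
  expect_identical(nrow(rank_and_select(recs, u, 0L)), 0L)
  expect_error(rank_and_select(recs, u, 4L), class = "codonopt_config_error")
  # ties: equal CAI breaks by longer CDS then id
  tie <- gene_records(c("zz", "aa", "bb"),
                      nt = c(strrep("CTG", 10), strrep("CTG", 12),
                             strrep("CTG", 10)))
  expect_identical(rank_and_select(tie, u, 3L)$id, c("aa", "bb", "zz"))
})

test_that("the split reproduces the published 5184/741/1481 partition", {
  recs <- gene_records(sprintf("g%05d", 1:7406), aa = rep("MKT", 7406))
  parts <- split_dataset(recs, c(0.7, 0.1, 0.2), seed = 11)
  expect_identical(vapply(parts, nrow, integer(1)),
                   c(train = 5184L, validation = 741L, test = 1481L))
  expect_identical(sort(c(parts$train$id, parts$validation$id,
                          parts$test$id)), sort(recs$id))
})

test_that("splits are exact partitions, deterministic, and size-correct", {
  small <- gene_records(sprintf("s%02d", 1:10), aa = rep("MK", 10))
  p <- split_dataset(small, c(0.7, 0.1, 0.2), seed = 3)
  expect_identical(vapply(p, nrow, integer(1)),
                   c(train = 7L, validation = 1L, test = 2L))
  p2 <- split_dataset(small, c(0.7, 0.1, 0.2), seed = 3)
  expect_identical(p, p2)
  for (n in c(1L, 7L, 23L, 100L)) {
    recs <- gene_records(sprintf("r%03d", seq_len(n)), aa = rep("M", n))
    parts <- split_dataset(recs, c(0.6, 0.2, 0.2), seed = n)
    ids <- c(parts$train$id, parts$validation$id, parts$test$id)
    expect_identical(sort(ids), sort(recs$id))
    expect_identical(anyDuplicated(ids), 0L)
  }
  p0 <- split_dataset(gene_records(character(0)), seed = 1)
  expect_true(all(vapply(p0, nrow, integer(1)) == 0L))
  expect_error(split_dataset(small, c(0.5, 0.5, 0.5)),
               class = "codonopt_config_error")
})

test_that("the curation pipeline composes monotonically with a log", {
  host <- make_host(seed = 3, context_order = 0L, bias_strength = 0.4)
  genes <- sample_genes(host, 30, list(min_aa = 60L, max_aa = 140L), seed = 5)
  res <- curate(genes, host_usage_table(host), min_aa_length = 90L, seed = 2)
  n_sel <- nrow(res$train) + nrow(res$validation) + nrow(res$test)
  n_kept <- sum(!is.na(res$log$cluster))
  expect_lte(n_sel, n_kept)
  expect_lte(n_kept, nrow(genes))
  expect_identical(nrow(res$log), nrow(genes))
  expect_setequal(stats::na.omit(res$log$partition),
                  c("train", "validation", "test"))
  # records shorter than the floor never reach a partition
  expect_true(all(is.na(res$log$partition[res$log$length_aa < 90])))
})
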