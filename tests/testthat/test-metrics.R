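test_that("relative adaptiveness normalizes within families with a floor", {
  counts <- stats::setNames(rep(1, 61), sense_codons())
  counts[synonymous_codons("K")] <- c(75, 25)     # AAA, AAG
  w <- relative_adaptiveness(codon_usage(counts))
  expect_equal(unname(w$w["AAA"]), 1)
  expect_equal(unname(w$w["AAG"]), 1 / 3)
  # zero-count codon in a live family floors at 1e-4
  counts[synonymous_codons("K")] <- c(10, 0)
  w2 <- relative_adaptiveness(codon_usage(counts))
  expect_identical(unname(w2$w["AAG"]), 1e-4)
  # every family's most-used codon has w = 1
  u <- default_usage()
  w3 <- relative_adaptiveness(u)
  for (fam in genetic_code()$aa_to_codons) {
    expect_equal(max(w3$w[fam]), 1)
  }
  # all-zero family: NA weights, error only when actually scored
  counts[synonymous_codons("K")] <- 0
  w4 <- relative_adaptiveness(codon_usage(counts))
  expect_true(all(is.na(w4$w[synonymous_codons("K")])))
  expect_error(cai("AAA", w4), class = "codonopt_degenerate_usage")
  expect_silent(cai("TTT", w4))
})

test_that("CAI is the geometric mean over scorable codons", {
  counts <- stats::setNames(rep(1, 61), sense_codons())
  counts[synonymous_codons("K")] <- c(75, 25)
  w <- relative_adaptiveness(codon_usage(counts))
  # two scorable codons with w = 1 and 1/3: CAI = sqrt(1/3)
  expect_equal(cai("AAAAAG", w), sqrt(1 / 3), tolerance = 1e-12)
  # ATG/TGG and stops are excluded from the mean
  expect_equal(cai("ATGAAAAAGTGGTAA", w), sqrt(1 / 3), tolerance = 1e-12)
  expect_error(cai("ATGTGG", w), class = "codonopt_undefined_value")
  # order invariance of the geometric mean
  withr::with_seed(2, {
    s <- random_cds(30)
    perm <- paste(sample(codonopt:::split_codons(s)), collapse = "")
  })
  w2 <- relative_adaptiveness(default_usage())
  expect_equal(cai(s, w2), cai(perm, w2), tolerance = 1e-12)
  expect_true(cai(s, w2) > 0 && cai(s, w2) <= 1)
})

test_that("GC-content is the G+C percentage", {
  expect_identical(gc_content("ATGC"), 50)
  expect_identical(gc_content("GGCC"), 100)
  expect_identical(gc_content("ATAT"), 0)
  expect_error(gc_content(""), class = "codonopt_undefined_value")
})

test_that("CFD counts codons strictly below the rarity threshold", {
  counts <- stats::setNames(rep(1, 61), sense_codons())
  counts[synonymous_codons("K")] <- c(100, 25)   # w(AAG) = 0.25
  counts[synonymous_codons("N")] <- c(100, 30)   # w(AAT) = 0.30 exactly
  w <- relative_adaptiveness(codon_usage(counts))
  expect_identical(cfd("AAAAAG", w), 50)
  expect_identical(cfd("AACAAT", w), 0)           # 0.30 is not < 0.30
  u <- default_usage()
  expect_identical(cfd(hfc_optimize(random_protein(40), u),
                       relative_adaptiveness(u)), 0)
})

test_that("repeat counting matches the exhaustive oracle", {
  expect_identical(negative_repeats("ACGTACGT", 10L), 0L)
  # a 12-nt block planted twice in a repeat-free background
  withr::with_seed(40, {
    found <- FALSE
    while (!found) {
      bg <- random_dna(120)
      block <- random_dna(12)
      s <- paste0(substr(bg, 1, 50), block, substr(bg, 51, 100), block)
      found <- oracle_repeats(paste0(substr(bg, 1, 50), "X",
                                     substr(bg, 51, 100)), 10L) == 0L
    }
    expect_identical(negative_repeats(s), oracle_repeats(s))
    expect_gte(negative_repeats(s), 1L)
  })
  # random and adversarial instances against the brute-force oracle
  withr::with_seed(41, {
    for (trial in 1:25) {
      s <- random_dna(sample(40:220, 1))
      if (trial %% 2 == 0) {     # plant overlapping/nested repeats
        piece <- substr(s, 1, sample(10:25, 1))
        s <- paste0(s, piece, substr(piece, 1, 11))
      }
      expect_identical(negative_repeats(s), oracle_repeats(s))
    }
    # tandem homopolymer: heavily overlapping occurrences
    expect_identical(negative_repeats(strrep("A", 30)),
                     oracle_repeats(strrep("A", 30)))
  })
})

test_that("cis-element counting covers both strands and overlaps", {
  bg <- "ATGCATCCATCGATCGATCGCATCATCGTACG"
  s <- paste0(bg, "AGGAGG", bg)
  counts <- negative_cis_elements(s)
  expect_gte(counts, 1L)
  # the full Shine-Dalgarno motif itself contributes exactly once
  expect_identical(negative_cis_elements(s, c(sd = "AGGAGG")), 1L)
  expect_identical(negative_cis_elements(s, character(0)), 0L)
  # motif present on the reverse strand only is counted once
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GCTGGTGG")))
  s2 <- paste0(bg, rc, bg)
  expect_identical(negative_cis_elements(s2, c(chi = "GCTGGTGG")), 1L)
  # overlapping homopolymer hits all count (3 overlapping starts in 10 nt)
  expect_identical(negative_cis_elements(strrep("A", 10), c(a8 = "AAAAAAAA")),
                   3L)
  expect_error(negative_cis_elements("ACGT", c(bad = "AQQ")),
               class = "codonopt_config_error")
})

test_that("mutational rate counts amino-acid mismatches", {
  p <- random_protein(100)
  expect_identical(mutational_rate(p, hfc_optimize(p, default_usage())), 0)
  # one altered residue in 100
  res <- strsplit(p, "")[[1]]
  res[37] <- if (res[37] == "K") "E" else "K"
  altered <- hfc_optimize(paste(res, collapse = ""), default_usage())
  expect_identical(mutational_rate(p, altered), 1)
  expect_error(mutational_rate("MK", "ATG"), class = "codonopt_data_error")
})

test_that("mean degeneracy averages family sizes", {
  expect_identical(mean_degeneracy("M"), 1)
  expect_identical(mean_degeneracy("L"), 6)
  all20 <- paste(names(codonopt:::family_sizes()), collapse = "")
  expect_identical(mean_degeneracy(all20), 61 / 20)
  expect_error(mean_degeneracy(""), class = "codonopt_undefined_value")
})

test_that("evaluation reports reproduce hand-computed statistics", {
  u <- default_usage()
  w <- relative_adaptiveness(u)
  withr::with_seed(9, {
    recs <- gene_records(c("m1", "m2", "m3"),
                         nt = replicate(3, random_cds(60)))
  })
  rep <- evaluate(recs, c("original", "hfc", "urc"), u, seed = 4)
  expect_identical(nrow(rep$per_sequence), 9L)
  # summary means equal recomputed column means
  for (m in c("original", "hfc", "urc")) {
    sub <- rep$per_sequence[rep$per_sequence$method == m, ]
    expect_equal(
      rep$summary$mean[rep$summary$method == m & rep$summary$metric == "cai"],
      mean(sub$cai))
  }
  # hand-check the original rows against direct metric calls
  expect_equal(rep$per_sequence$cai[rep$per_sequence$method == "original"],
               vapply(recs$nt, cai, numeric(1), w = w, USE.NAMES = FALSE))
  hfc_rows <- rep$per_sequence[rep$per_sequence$method == "hfc", ]
  expect_true(all(hfc_rows$cai == 1))
  expect_true(all(hfc_rows$cfd == 0))
  expect_true(all(rep$per_sequence$mutational_rate == 0))
  expect_identical(rep$tests$reference, rep(c("original"), 2))
  expect_true(all(rep$tests$p_cai_t >= 0 & rep$tests$p_cai_t <= 1,
                  na.rm = TRUE))
})
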