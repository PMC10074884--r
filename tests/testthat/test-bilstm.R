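test_that("configuration validation names the offending field", {
  expect_error(optimizer_config(hidden_units = 0), "hidden_units",
               class = "codonopt_config_error")
  expect_error(optimizer_config(dropout = 1), "dropout",
               class = "codonopt_config_error")
  expect_error(optimizer_config(epochs = 0), "epochs",
               class = "codonopt_config_error")
  cfg <- test_profile(seed = 2)
  expect_identical(cfg$hidden_units, 64L)
  expect_identical(cfg$recurrent_layers, 1L)
  expect_identical(cfg$epochs, 10L)
})

test_that("model building is shape-correct and seed-deterministic", {
  cfg <- optimizer_config(hidden_units = 8, recurrent_layers = 2, seed = 7)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_model(optimizer_config(hidden_units = 8, recurrent_layers = 2,
                                     seed = 8))
  expect_false(identical(m1$weights, m3$weights))
  s <- predict_scores(m1, "MKTAY")
  expect_identical(dim(s), c(5L, 64L))
  expect_equal(unname(rowSums(s)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(s >= 0))
  # nlft encoding changes the input width only
  m4 <- build_model(optimizer_config(hidden_units = 8, encoding = "nlft"))
  expect_identical(ncol(m4$weights$layers[[1]]$Wx_f), 18L)
})

test_that("inference is deterministic and handles the empty sequence", {
  m <- build_model(test_profile(hidden_units = 8, seed = 1))
  expect_identical(predict_scores(m, "MKWY"), predict_scores(m, "MKWY"))
  e <- predict_scores(m, "")
  expect_identical(dim(e), c(0L, 64L))
  expect_identical(optimize_sequence(m, ""), "")
  expect_error(predict_scores(m, "M?"), class = "codonopt_alphabet_error")
})

test_that("analytic gradients match finite differences", {
  cfg <- optimizer_config(hidden_units = 4, recurrent_layers = 2,
                          dropout = 0, l2_penalty = 1e-3, seed = 42)
  m <- build_model(cfg)
  withr::with_seed(1, {
    X <- list(matrix(stats::runif(4 * 26), 4, 26),
              matrix(stats::runif(3 * 26), 3, 26))
    y <- list(sample(64, 4, TRUE), sample(64, 3, TRUE))
  })
  lg <- codonopt:::cpp_bilstm_loss_grad(m$weights, X, y, 1e-3)
  fd <- function(setter, getter, eps = 1e-6) {
    wp <- setter(m$weights, getter(m$weights) + eps)
    wm <- setter(m$weights, getter(m$weights) - eps)
    (codonopt:::cpp_bilstm_loss_grad(wp, X, y, 1e-3)$loss -
     codonopt:::cpp_bilstm_loss_grad(wm, X, y, 1e-3)$loss) / (2 * eps)
  }
  withr::with_seed(2, {
    for (trial in 1:12) {
      l <- sample(2, 1)
      nm <- sample(c("Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b"), 1)
      i <- sample(length(m$weights$layers[[l]][[nm]]), 1)
      g_num <- fd(function(w, v) { w$layers[[l]][[nm]][i] <- v; w },
                  function(w) w$layers[[l]][[nm]][i])
      expect_equal(lg$grads$layers[[l]][[nm]][i], g_num, tolerance = 1e-4)
    }
    i <- sample(length(m$weights$V), 1)
    g_num <- fd(function(w, v) { w$V[i] <- v; w }, function(w) w$V[i])
    expect_equal(lg$grads$V[i], g_num, tolerance = 1e-4)
  })
})

test_that("constrained decoding is synonymous; unconstrained can mutate", {
  # uniform scores: constrained picks the lexicographically first codon
  scores <- matrix(1 / 64, nrow = 2, ncol = 64,
                   dimnames = list(NULL, codonopt:::CODONS))
  expect_identical(decode_codons(scores, "LK"),
                   paste0(synonymous_codons("L")[1], synonymous_codons("K")[1]))
  # mass on a non-synonymous class flips the unconstrained translation
  s2 <- matrix(0, nrow = 1, ncol = 64,
               dimnames = list(NULL, codonopt:::CODONS))
  s2[1, "GAA"] <- 1   # E, but the input residue is Q
  expect_identical(decode_codons(s2, "Q", mode = "unconstrained"), "GAA")
  expect_gt(mutational_rate("Q", decode_codons(s2, "Q", "unconstrained")), 0)
  expect_identical(translate(decode_codons(s2, "Q")), "Q")
  expect_error(decode_codons(scores, "LKM"), class = "codonopt_data_error")
})

test_that("an untrained model already satisfies the no-mutation contract", {
  m <- build_model(test_profile(hidden_units = 8, seed = 3))
  withr::with_seed(4, {
    for (i in 1:5) {
      p <- random_protein(sample(10:50, 1))
      out <- optimize_sequence(m, p)
      expect_identical(nchar(out), 3L * nchar(p))
      expect_identical(translate(out), p)
      expect_identical(mutational_rate(p, out), 0)
    }
  })
})

test_that("the model memorizes a deterministic codon assignment", {
  # point-mass host: each amino acid always coded by one fixed codon, a
  # learnable deterministic function
  host <- make_host(seed = 5, context_order = 0, bias_strength = 1)
  genes <- sample_genes(host, 60, list(min_aa = 30, max_aa = 60), seed = 2)
  cfg <- test_profile(hidden_units = 32, epochs = 12, seed = 9)
  model <- cached_model("memorize", function() {
    train_optimizer(genes[1:40, ], NULL, cfg)
  })
  acc <- codonopt:::codon_match_accuracy(model, genes[41:60, ])
  expect_identical(acc, 1)
  # trainability smoke: later training loss no worse than the first epoch
  expect_lte(utils::tail(model$history$train_loss, 1),
             model$history$train_loss[1])
  expect_identical(nrow(model$history), cfg$epochs)
  # the model reproduces the fixture's codons exactly
  aa <- translate(codonopt:::strip_terminal_stop(genes$nt[50]))
  expect_identical(optimize_sequence(model, aa),
                   codonopt:::strip_terminal_stop(genes$nt[50]))
})

test_that("training errors on empty or inconsistent data", {
  expect_error(train_optimizer(gene_records(character(0)), NULL,
                               test_profile()),
               class = "codonopt_data_error")
  no_cds <- gene_records("x", aa = "MKT")
  expect_error(train_optimizer(no_cds, NULL, test_profile()),
               class = "codonopt_data_error")
})

test_that("model archives round-trip bit-identically with metadata", {
  host <- make_host(seed = 5, context_order = 0, bias_strength = 1)
  genes <- sample_genes(host, 10, list(min_aa = 20, max_aa = 30), seed = 2)
  m <- train_optimizer(genes, NULL,
                       test_profile(hidden_units = 8, epochs = 2, seed = 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  probe <- "MKTAYIAKQRQISFVKSHFSRQ"
  expect_identical(predict_scores(m, probe), predict_scores(m2, probe))
  expect_identical(m2$config, m$config)
  expect_identical(m2$alphabet, m$alphabet)
  # truncated archive is a format error
  raw_bytes <- readBin(f, "raw", file.info(f)$size)
  f2 <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw_bytes[1:20], f2)
  expect_error(load_model(f2), class = "codonopt_format_error")
  expect_error(load_model(tempfile()), class = "codonopt_format_error")
})
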