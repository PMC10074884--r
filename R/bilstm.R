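# User-facing surface of the neural codon optimizer: configuration, weight
# initialization, training, inference, constrained decoding, serialization.

MODEL_FORMAT_VERSION <- 1L

#' Configuration of the neural codon optimizer
#'
#' Hyperparameters of the bidirectional LSTM codon classifier. The default
#' profile (2 stacked bidirectional layers of 256 units per direction,
#' dropout 0.2, L2 1e-4, Adam at 1e-3, batch 32, 50 epochs) targets
#' full-scale host corpora; [test_profile()] is a small fast profile for
#' unit-scale experiments.
#'
#' @param hidden_units LSTM units per direction (>= 1).
#' @param recurrent_layers Number of stacked bidirectional layers (>= 1).
#' @param dropout Dropout fraction on layer outputs, in [0, 1).
#' @param l2_penalty L2 regularization strength on weight matrices.
#' @param learning_rate Adam step size.
#' @param batch_size Sequences per gradient step.
#' @param epochs Training epochs (>= 1).
#' @param encoding Input encoding, `"onehot"` (26 features) or `"nlft"`
#'   (18 features).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(hidden_units = 256L, recurrent_layers = 2L,
                             dropout = 0.2, l2_penalty = 1e-4,
                             learning_rate = 1e-3, batch_size = 32L,
                             epochs = 50L, encoding = c("onehot", "nlft"),
                             seed = 1L) {
  encoding <- match.arg(encoding)
  check <- function(ok, field) {
    if (!ok) abort_config(sprintf("invalid config field '%s'", field))
  }
  check(is.numeric(hidden_units) && hidden_units >= 1, "hidden_units")
  check(is.numeric(recurrent_layers) && recurrent_layers >= 1,
        "recurrent_layers")
  check(is.numeric(dropout) && dropout >= 0 && dropout < 1, "dropout")
  check(is.numeric(l2_penalty) && l2_penalty >= 0, "l2_penalty")
  check(is.numeric(learning_rate) && learning_rate > 0, "learning_rate")
  check(is.numeric(batch_size) && batch_size >= 1, "batch_size")
  check(is.numeric(epochs) && epochs >= 1, "epochs")
  structure(
    list(hidden_units = as.integer(hidden_units),
         recurrent_layers = as.integer(recurrent_layers),
         dropout = dropout, l2_penalty = l2_penalty,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), encoding = encoding,
         seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

#' Small training profile for fast experiments
#'
#' @param ... Overrides passed to [optimizer_config()].
#' @return An `optimizer_config` with 64 units, 1 layer, 10 epochs, batch
#'   16 and a larger Adam step (5e-3): the small model takes few gradient
#'   steps per run, so a larger step size is needed to converge within its
#'   short schedule.
#' @export
test_profile <- function(...) {
  defaults <- list(hidden_units = 64L, recurrent_layers = 1L, epochs = 10L,
                   batch_size = 16L, learning_rate = 5e-3)
  args <- utils::modifyList(defaults, list(...))
  do.call(optimizer_config, args)
}

n_input_features <- function(encoding) {
  if (encoding == "onehot") 26L else 18L
}

# Seeded parameter initialization: uniform(-s, s) with s = 1/sqrt(fan-in),
# forget-gate biases at 1 (standard LSTM practice).
init_weights <- function(config, alphabet = alphabet_spec()) {
  H <- config$hidden_units
  L <- config$recurrent_layers
  n_out <- 64L
  withr::with_seed(config$seed, {
    mk <- function(r, c) {
      s <- 1 / sqrt(c)
      matrix(stats::runif(r * c, -s, s), r, c)
    }
    mkb <- function() {
      b <- matrix(0, 4L * H, 1L)
      b[(H + 1L):(2L * H), 1L] <- 1   # forget gate bias
      b
    }
    layers <- lapply(seq_len(L), function(l) {
      f_in <- if (l == 1L) n_input_features(config$encoding) else 2L * H
      list(Wx_f = mk(4L * H, f_in), Wh_f = mk(4L * H, H), b_f = mkb(),
           Wx_b = mk(4L * H, f_in), Wh_b = mk(4L * H, H), b_b = mkb())
    })
    list(layers = layers, V = mk(n_out, 2L * H),
         c = matrix(0, n_out, 1L))
  })
}

#' Build an untrained model
#'
#' Instantiates the architecture — stacked bidirectional LSTM layers over
#' the per-residue features, a dense projection to the 64-codon label space
#' and a per-position softmax — with seeded initial parameters.
#'
#' @param config An `optimizer_config`.
#' @param alphabet An `alphabet_spec`.
#' @return Object of class `codon_optimizer` (untrained: empty history).
#' @export
build_model <- function(config = optimizer_config(),
                        alphabet = alphabet_spec()) {
  if (!inherits(config, "optimizer_config")) {
    abort_config("config must be an optimizer_config")
  }
  structure(
    list(weights = init_weights(config, alphabet), config = config,
         alphabet = alphabet, history = NULL,
         version = MODEL_FORMAT_VERSION),
    class = "codon_optimizer"
  )
}

records_to_tensors <- function(records, config, alphabet) {
  X <- vector("list", nrow(records))
  y <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    eg <- encode_gene(records[i, , drop = FALSE], config$encoding, alphabet)
    if (is.null(eg$labels)) {
      abort_data(sprintf("record '%s' has no CDS to supervise on",
                         records$id[i]))
    }
    X[[i]] <- eg$features
    y[[i]] <- eg$labels
  }
  list(X = X, y = y)
}

#' Train the neural codon optimizer
#'
#' Minimizes per-position cross-entropy between predicted codon classes and
#' the host's observed codons, with L2 regularization and dropout, using
#' Adam over shuffled mini-batches (gradients accumulated per sequence, so
#' no padding is involved). The parameters with the best validation loss
#' are retained; the per-epoch history (loss and codon-match accuracy on
#' both sets) is stored on the model.
#'
#' @param train_records `gene_records` with CDS (training supervision).
#' @param val_records Optional `gene_records` for validation (may be
#'   `NULL`).
#' @param config An `optimizer_config`.
#' @param alphabet An `alphabet_spec`.
#' @return A trained `codon_optimizer`.
#' @export
train_optimizer <- function(train_records, val_records = NULL,
                            config = optimizer_config(),
                            alphabet = alphabet_spec()) {
  if (is.null(train_records) || nrow(train_records) == 0L) {
    abort_data("empty training set")
  }
  model <- build_model(config, alphabet)
  tr <- records_to_tensors(train_records, config, alphabet)
  va <- if (!is.null(val_records) && nrow(val_records) > 0L) {
    records_to_tensors(val_records, config, alphabet)
  } else {
    list(X = list(), y = list())
  }
  fit <- withr::with_seed(config$seed + 1L, {
    cpp_bilstm_train(model$weights, tr$X, tr$y, va$X, va$y,
                     config$epochs, config$learning_rate, config$l2_penalty,
                     config$dropout, config$batch_size)
  })
  model$weights <- fit$weights
  model$history <- tibble::as_tibble(fit$history)
  model
}

#' Per-position codon class probabilities
#'
#' Runs the trained network over a protein and returns, for every residue,
#' a probability distribution over the 64 codon classes. Inference is
#' deterministic (dropout disabled).
#'
#' @param model A `codon_optimizer`.
#' @param aa_seq Amino-acid sequence.
#' @return Numeric matrix T x 64; rows sum to 1; columns named by codon.
#' @export
predict_scores <- function(model, aa_seq) {
  if (!inherits(model, "codon_optimizer")) abort_config("not a codon_optimizer")
  if (nchar(aa_seq) == 0L) {
    m <- matrix(numeric(0), 0L, 64L, dimnames = list(NULL, CODONS))
    return(m)
  }
  X <- encode_features(aa_seq, model$config$encoding, model$alphabet)
  probs <- cpp_bilstm_predict(model$weights, X)
  colnames(probs) <- CODONS
  probs
}

#' Decode codon scores into a coding sequence
#'
#' Constrained mode (the default) restricts every position's argmax to the
#' synonymous family of its amino acid, guaranteeing
#' `translate(result) == aa_seq` and hence a 0% mutational rate.
#' Unconstrained mode takes the global argmax per position — the raw
#' classifier behaviour, which can in principle emit non-synonymous
#' codons. Ties break to the lexicographically smaller codon.
#'
#' @param scores T x 64 score matrix (rows align with `aa_seq` positions).
#' @param aa_seq Amino-acid sequence.
#' @param mode `"constrained"` or `"unconstrained"`.
#' @param code A `genetic_code` object.
#' @return A CDS of length `3 * nchar(aa_seq)`.
#' @export
decode_codons <- function(scores, aa_seq, mode = c("constrained",
                                                   "unconstrained"),
                          code = std_code()) {
  mode <- match.arg(mode)
  res <- aa_positions(aa_seq, code)
  if (nrow(scores) != length(res) || ncol(scores) != 64L) {
    abort_data(sprintf("score matrix is %dx%d, expected %dx64",
                       nrow(scores), ncol(scores), length(res)))
  }
  if (length(res) == 0L) return("")
  out <- character(length(res))
  for (t in seq_along(res)) {
    if (mode == "constrained") {
      fam <- synonymous_codons(res[t], code)
      out[t] <- fam[which.max(scores[t, fam])]
    } else {
      out[t] <- CODONS[which.max(scores[t, ])]
    }
  }
  paste(out, collapse = "")
}

#' Optimize a protein with the trained model
#'
#' Encode, score, decode: the end-to-end neural optimization of one
#' protein. With the default constrained decoding the output always
#' back-translates to the input.
#'
#' @param model A trained `codon_optimizer`.
#' @param aa_seq Amino-acid sequence.
#' @param mode Decoding mode, see [decode_codons()].
#' @return A CDS of length `3 * nchar(aa_seq)`.
#' @export
optimize_sequence <- function(model, aa_seq, mode = "constrained") {
  decode_codons(predict_scores(model, aa_seq), aa_seq, mode)
}

#' Save / load a trained optimizer
#'
#' The archive is a single-file versioned container holding the weights,
#' configuration, alphabet and training history; a loaded model predicts
#' identically to the saved one.
#'
#' @param model A `codon_optimizer`.
#' @param path Archive path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "codon_optimizer")) abort_config("not a codon_optimizer")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such archive: %s", path))
  model <- tryCatch(readRDS(path),
                    error = function(e) abort_format(
                      sprintf("corrupt model archive '%s': %s", path,
                              conditionMessage(e))))
  if (!inherits(model, "codon_optimizer")) {
    abort_format("archive does not contain a codon optimizer")
  }
  if (!identical(model$version, MODEL_FORMAT_VERSION)) {
    co_abort(sprintf("model format version %s unsupported (expected %d)",
                     model$version, MODEL_FORMAT_VERSION),
             "codonopt_version_error")
  }
  model
}

#' @export
print.codon_optimizer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<codon_optimizer> %d-layer BiLSTM, %d units/direction, %s encoding (%s)\n",
    cfg$recurrent_layers, cfg$hidden_units, cfg$encoding,
    if (is.null(x$history)) "untrained" else
      sprintf("trained %d epochs", nrow(x$history))))
  invisible(x)
}

# Codon-match accuracy of the model against reference CDS records: the
# fraction of positions where the constrained prediction equals the codon
# actually used.
codon_match_accuracy <- function(model, records) {
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(records))) {
    nt <- strip_terminal_stop(records$nt[i])
    aa <- translate(nt)
    pred <- split_codons(optimize_sequence(model, aa))
    ref <- split_codons(nt)
    hits <- hits + sum(pred == ref)
    total <- total + length(ref)
  }
  hits / total
}
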