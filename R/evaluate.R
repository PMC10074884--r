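# Comparison harness: run a set of optimizers over a gene collection and
# score every output with the full metric suite.

EVAL_METHODS <- c("original", "urc", "bfc", "hfc", "erc", "neural")

optimize_with_method <- function(method, aa, nt, usage, model, k, seed) {
  switch(method,
    original = {
      if (is.na(nt)) abort_data("method 'original' needs nt sequences")
      strip_terminal_stop(nt)
    },
    urc = urc_optimize(aa, seed = seed),
    bfc = bfc_optimize(aa, usage, seed = seed),
    hfc = hfc_optimize(aa, usage),
    erc = erc_optimize(aa, usage, k = k, seed = seed),
    neural = {
      if (is.null(model)) abort_config("method 'neural' needs a model")
      optimize_sequence(model, aa)
    },
    abort_config(sprintf("unknown method '%s'", method))
  )
}

#' Evaluate optimization methods on a gene collection
#'
#' Optimizes every record with every requested method and scores each
#' output on CAI, GC-content, rare-codon percentage (CFD), negative repeat
#' elements, negative cis-regulatory motifs and mutational rate. Summary
#' statistics and pairwise significance tests against a reference method
#' (two-sample t-test on CAI; two-sided Mann-Whitney U on the repeat and
#' cis-element counts) are included.
#'
#' @param records A `gene_records` tibble (CDS required for method
#'   `"original"`; otherwise proteins suffice).
#' @param methods Character subset of
#'   `c("original","urc","bfc","hfc","erc","neural")`.
#' @param usage A `codon_usage` object (weights source).
#' @param model A trained `codon_optimizer`; required when `"neural"` is
#'   requested.
#' @param erc_k Candidate count for ERC (default 100 at evaluation scale).
#' @param seed Base seed for the stochastic methods.
#' @param motifs Cis-regulatory motif set.
#' @param reference Method that the pairwise tests compare against
#'   (default: `"original"` when present, else the first method).
#' @return Object of class `evaluation_report`: `per_sequence` (tidy tibble:
#'   id, method, one column per metric), `summary` (method x metric means
#'   and SDs) and `tests` (pairwise test results).
#' @export
evaluate <- function(records, methods = c("original", "urc", "bfc", "hfc"),
                     usage = default_usage(), model = NULL, erc_k = 100L,
                     seed = 1L, motifs = default_cis_motifs(),
                     reference = NULL) {
  methods <- match.arg(methods, EVAL_METHODS, several.ok = TRUE)
  if (nrow(records) == 0L) abort_data("no records to evaluate")
  weights <- relative_adaptiveness(usage)
  aa <- record_aa(records)
  rows <- list()
  for (m in methods) {
    for (i in seq_len(nrow(records))) {
      nt_opt <- optimize_with_method(m, aa[i], records$nt[i], usage, model,
                                     erc_k, seed + i)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = records$id[i], method = m,
        cai = cai(nt_opt, weights),
        gc = gc_content(nt_opt),
        cfd = cfd(nt_opt, weights),
        repeats = negative_repeats(nt_opt),
        cis_elements = negative_cis_elements(nt_opt, motifs),
        mutational_rate = mutational_rate(aa[i], nt_opt))
    }
  }
  per_seq <- do.call(rbind, rows)
  metric_cols <- c("cai", "gc", "cfd", "repeats", "cis_elements",
                   "mutational_rate")
  summ <- do.call(rbind, lapply(methods, function(m) {
    sub <- per_seq[per_seq$method == m, ]
    tibble::tibble(method = m, metric = metric_cols,
                   mean = vapply(metric_cols, function(k) mean(sub[[k]]),
                                 numeric(1), USE.NAMES = FALSE),
                   sd = vapply(metric_cols, function(k) stats::sd(sub[[k]]),
                               numeric(1), USE.NAMES = FALSE))
  }))
  if (is.null(reference)) {
    reference <- if ("original" %in% methods) "original" else methods[1]
  }
  tests <- NULL
  others <- setdiff(methods, reference)
  if (length(others) && nrow(records) >= 2L) {
    ref <- per_seq[per_seq$method == reference, ]
    tests <- do.call(rbind, lapply(others, function(m) {
      sub <- per_seq[per_seq$method == m, ]
      t_cai <- tryCatch(stats::t.test(sub$cai, ref$cai)$p.value,
                        error = function(e) NA_real_)
      u_rep <- tryCatch(
        suppressWarnings(stats::wilcox.test(sub$repeats, ref$repeats))$p.value,
        error = function(e) NA_real_)
      u_cis <- tryCatch(
        suppressWarnings(stats::wilcox.test(sub$cis_elements,
                                            ref$cis_elements))$p.value,
        error = function(e) NA_real_)
      tibble::tibble(method = m, reference = reference,
                     p_cai_t = t_cai, p_repeats_u = u_rep,
                     p_cis_u = u_cis)
    }))
  }
  structure(list(per_sequence = per_seq, summary = summ, tests = tests),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  means <- x$summary[x$summary$metric %in% c("cai", "gc", "cfd"), ]
  print(as.data.frame(means), row.names = FALSE)
  invisible(x)
}
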