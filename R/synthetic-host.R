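# Synthetic host genomes with controllable, optionally context-dependent
# synonymous codon usage. Used for training fixtures, parameter-recovery
# tests, and the benchmark-shaped evaluation set.

# Proteome-average amino-acid composition (E. coli-like, fractions sum to 1).
# Fixed package data: gives a realistic degeneracy mix.
AA_COMPOSITION <- c(
  A = 0.095, R = 0.055, N = 0.039, D = 0.054, C = 0.012,
  Q = 0.044, E = 0.058, G = 0.074, H = 0.022, I = 0.060,
  L = 0.107, K = 0.044, M = 0.028, F = 0.039, P = 0.044,
  S = 0.058, T = 0.054, W = 0.015, Y = 0.028, V = 0.071
)
AA_COMPOSITION <- AA_COMPOSITION / sum(AA_COMPOSITION)

# Contexts for order-1 hosts: previous amino acid, or "^" at the first codon.
HOST_CONTEXTS <- c(names(AA_COMPOSITION), "^")

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (sum(g) <= 0) g <- rep(1, k)   # numerical underflow at tiny conc
  g / sum(g)
}

# Concentration from bias strength: bias -> 1 gives near-point-mass family
# distributions, bias -> 0 near-uniform ones.
bias_to_conc <- function(bias_strength) {
  2 * (1 - bias_strength) / max(bias_strength, 1e-6)
}

#' Generate a synthetic host model
#'
#' Draws, reproducibly from a seed, a generative model of synonymous codon
#' choice: for every amino-acid family one codon distribution (context order
#' 0) or one distribution per previous amino acid (order 1, with a start
#' context `"^"`). Distributions are Dirichlet draws whose concentration is
#' controlled by `bias_strength`: near 1 gives near-deterministic codon
#' choice per context, near 0 near-uniform choice. Order-1 hosts are
#' redrawn until at least one family's conditional distributions differ
#' across contexts by total variation > 0.2, so context genuinely matters.
#'
#' @param seed Integer seed.
#' @param context_order 0 (frequency-only host) or 1 (previous-residue
#'   context).
#' @param bias_strength Concentration control in (0, 1].
#' @param code A `genetic_code` object.
#' @return Object of class `synthetic_host`: `context_order`,
#'   `bias_strength`, `tables` (per amino acid, a contexts x codons row-
#'   stochastic matrix), `aa_composition`, `seed`.
#' @export
make_host <- function(seed = 1L, context_order = 1L, bias_strength = 0.6,
                      code = std_code()) {
  if (!context_order %in% c(0L, 1L)) {
    abort_config("context_order must be 0 or 1")
  }
  if (bias_strength <= 0 || bias_strength > 1) {
    abort_config("bias_strength must be in (0, 1]")
  }
  conc <- bias_to_conc(bias_strength)
  fams <- code$aa_to_codons
  draw <- function() {
    lapply(fams, function(fam) {
      k <- length(fam)
      ctx <- if (context_order == 0L) "." else HOST_CONTEXTS
      m <- t(vapply(ctx, function(cx) {
        if (bias_strength >= 1) {
          p <- numeric(k); p[sample.int(k, 1L)] <- 1; p
        } else {
          rdirichlet1(k, conc)
        }
      }, numeric(k)))
      # vapply with k = 1 returns a row vector; force contexts x codons
      if (k == 1L) m <- matrix(1, nrow = length(ctx), ncol = 1L)
      dimnames(m) <- list(ctx, fam)
      m
    })
  }
  context_gap <- function(tables) {
    max(vapply(tables, function(m) {
      if (nrow(m) < 2L || ncol(m) < 2L) return(0)
      g <- 0
      for (i in seq_len(nrow(m) - 1L)) {
        tv <- 0.5 * rowSums(abs(sweep(m[-seq_len(i), , drop = FALSE], 2,
                                      m[i, ])))
        g <- max(g, max(tv))
      }
      g
    }, numeric(1)))
  }
  tables <- withr::with_seed(seed, {
    t <- draw()
    if (context_order == 1L) {
      tries <- 1L
      while (context_gap(t) <= 0.2 && tries < 50L) {
        t <- draw()
        tries <- tries + 1L
      }
    }
    t
  })
  structure(
    list(context_order = as.integer(context_order),
         bias_strength = bias_strength,
         tables = tables,
         aa_composition = AA_COMPOSITION,
         seed = as.integer(seed)),
    class = "synthetic_host"
  )
}

# Conditional codon distribution for amino acid `aa` given previous residue
# `prev` ("^" at the first position).
host_conditional <- function(host, aa, prev) {
  m <- host$tables[[aa]]
  row <- if (host$context_order == 0L) 1L else prev
  stats::setNames(as.vector(m[row, , drop = FALSE]), colnames(m))
}

#' Sample genes from a synthetic host
#'
#' Draws protein sequences i.i.d. from the host's amino-acid composition
#' (lengths uniform over `[min_aa, max_aa]`) and codes them codon by codon
#' from the host's conditional choice tables. Every output is a valid CDS;
#' the FASTA-ready description records the generating parameters.
#'
#' @param host A `synthetic_host`.
#' @param n Number of genes.
#' @param length_spec List with `min_aa` (default 90) and `max_aa`
#'   (default 600).
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return A `gene_records` tibble with both `nt` and `aa` set.
#' @export
sample_genes <- function(host, n, length_spec = list(min_aa = 90L,
                                                     max_aa = 600L),
                         seed = 1L, prefix = "syn") {
  if (n == 0L) return(gene_records(character(0)))
  if (length_spec$min_aa < 1L || length_spec$max_aa < length_spec$min_aa) {
    abort_config("invalid length_spec")
  }
  aas <- names(host$aa_composition)
  desc <- sprintf("context_order=%d;bias=%g;host_seed=%d;seed=%d",
                  host$context_order, host$bias_strength, host$seed, seed)
  withr::with_seed(seed, {
    lens <- sample(seq(length_spec$min_aa, length_spec$max_aa), n,
                   replace = TRUE)
    nt <- character(n)
    aa <- character(n)
    for (g in seq_len(n)) {
      res <- sample(aas, lens[g], replace = TRUE,
                    prob = host$aa_composition)
      prev <- "^"
      codons <- character(lens[g])
      for (t in seq_len(lens[g])) {
        p <- host_conditional(host, res[t], prev)
        fam <- names(p)
        codons[t] <- if (length(fam) == 1L) fam else {
          fam[sample.int(length(fam), 1L, prob = p)]
        }
        prev <- res[t]
      }
      aa[g] <- paste(res, collapse = "")
      nt[g] <- paste(codons, collapse = "")
    }
    gene_records(sprintf("%s_gene_%04d", prefix, seq_len(n)),
                 nt = nt, aa = aa, description = desc)
  })
}

#' Analytic marginal usage table of a synthetic host
#'
#' Marginalizes the host's conditional codon-choice tables over the
#' amino-acid composition (order-1 contexts weighted by the composition;
#' the start context's O(1/length) contribution is ignored) and scales to a
#' usage table whose family fractions are the host's marginal conditionals.
#'
#' @param host A `synthetic_host`.
#' @return A `codon_usage` object.
#' @export
host_usage_table <- function(host) {
  comp <- host$aa_composition
  counts <- numeric(0)
  for (aa in names(host$tables)) {
    m <- host$tables[[aa]]
    marg <- if (host$context_order == 0L) {
      m[1L, ]
    } else {
      as.vector(comp %*% m[names(comp), , drop = FALSE])
    }
    names(marg) <- colnames(m)
    counts <- c(counts, marg * comp[aa] * 1e6)
  }
  codon_usage(counts)
}

#' Analytic accuracy ceilings for per-position codon prediction
#'
#' For genes sampled from a synthetic host, the expected per-position
#' accuracy of the best frequency-only (context-free) predictor — the
#' ceiling of what a background-frequency method can achieve — and of the
#' Bayes-optimal context-aware predictor. On an order-0 host the two
#' coincide; on an order-1 host the context ceiling is strictly higher
#' whenever context matters.
#'
#' @param host A `synthetic_host`.
#' @return List: `frequency` and `context`, both in (0, 1].
#' @export
accuracy_ceilings <- function(host) {
  comp <- host$aa_composition
  freq_acc <- 0
  ctx_acc <- 0
  for (aa in names(host$tables)) {
    m <- host$tables[[aa]]
    if (host$context_order == 0L) {
      best <- max(m[1L, ])
      freq_acc <- freq_acc + comp[aa] * best
      ctx_acc <- ctx_acc + comp[aa] * best
    } else {
      cond <- m[names(comp), , drop = FALSE]
      marg <- as.vector(comp %*% cond)
      # frequency-only predictor picks argmax of the marginal; it is right
      # with probability = that codon's conditional mass in each context
      freq_acc <- freq_acc + comp[aa] * sum(comp * cond[, which.max(marg)])
      ctx_acc <- ctx_acc + comp[aa] * sum(comp * apply(cond, 1, max))
    }
  }
  list(frequency = unname(freq_acc), context = unname(ctx_acc))
}

#' Benchmark-shaped synthetic fixture
#'
#' Forty CDS records emulating the shape of a published 40-gene expression
#' benchmark: mean length about 560 amino acids, sampled from a low-bias
#' (deliberately suboptimal) host so that every optimizer has headroom.
#'
#' @param seed Integer seed.
#' @return A `gene_records` tibble of 40 CDS.
#' @export
make_benchmark_fixture <- function(seed = 1L) {
  host <- make_host(seed = seed + 101L, context_order = 0L,
                    bias_strength = 0.2)
  sample_genes(host, 40L, length_spec = list(min_aa = 200L, max_aa = 925L),
               seed = seed, prefix = "bench")
}
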