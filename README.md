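# codonopt

Context-aware codon optimization for heterologous expression, in R.

## The problem

Because 61 sense codons encode only 20 amino acids, a protein has many
synonymous coding sequences, and expression hosts such as *E. coli* use
synonymous codons with strong, context-dependent bias. The industry
default — substituting every codon with its family's most frequent host
codon ("highest frequency choice", HFC) — drives the Codon Adaptation
Index to 1.0 by construction but produces genes unlike anything in the
host genome: real host genes use rare codons too, in patterned positions.

`codonopt` frames codon optimization as per-position sequence labeling. A
bidirectional LSTM reads the amino-acid sequence and predicts a
distribution over the 64 codon classes at every position; training on
host coding sequences teaches it the host's contextual codon preferences.
**Constrained decoding** restricts each position's argmax to the
synonymous family of its amino acid, so the optimized gene always
back-translates to the input protein exactly — a guaranteed 0.00%
mutational rate.

For a gene with per-position relative adaptiveness
`w(c) = f(c) / max f within the synonymous family`, the package scores

> CAI = (∏ᵢ w(cᵢ))^(1/N)

over scorable codons (stops and single-codon families excluded), along
with GC-content, the rare-codon percentage CFD (`w < 0.30`), negative
repeat elements, negative cis-regulatory motifs, and the mutational rate.
Four baseline optimizers (URC, BFC, HFC, ERC) and a curation pipeline
(length filter ≥ 90 aa, greedy >90%-identity de-redundancy, CAI ranking,
70/10/20 split) complete the toolkit. A synthetic host generator with
controllable context-dependent codon usage makes every claim testable
without downloads.

## Worked example

Train a small model on genes sampled from a synthetic host whose codon
choice depends on the previous residue, then compare optimizers:

```r
library(codonopt)

host  <- make_host(seed = 1, context_order = 1, bias_strength = 0.6)
genes <- sample_genes(host, 220, list(min_aa = 90, max_aa = 200), seed = 2)
usage <- host_usage_table(host)

model <- train_optimizer(genes[1:150, ], genes[151:170, ],
                         test_profile(seed = 3))
held_out <- genes[171:220, ]

evaluate(held_out[1:20, ], c("original", "urc", "bfc", "hfc", "neural"),
         usage, model = model, seed = 4)
#> <evaluation_report>
#>    method metric       mean         sd
#>  original    cai  0.8723764 0.01694406
#>  original     gc 50.3090972 3.51606300
#>  ...
#>       hfc    cai  1.0000000 0.00000000
#>       hfc     gc 60.0873474 3.75671904
#>    neural    cai  0.9161686 0.01352826
#>    neural     gc 52.0289572 2.87938774
```

HFC reaches CAI 1.0 exactly, as it must; the trained model lands at
0.916 — above the original genes (0.872) and the frequency-sampling
baseline (0.870) while staying closer to the host's actual usage than
wall-to-wall top codons, with GC-content (52%) well inside the 30–70%
band.

The synthetic host makes the context claim quantitative. The best
accuracy any frequency-only method can achieve at reproducing this
host's codon choices is analytically computable, as is the Bayes-optimal
context-aware ceiling:

```r
codonopt:::codon_match_accuracy(model, held_out)
#> 0.523
accuracy_ceilings(host)
#> frequency-only ceiling: 0.401   context ceiling: 0.576
```

The model recovers most of the context signal that frequency tables
cannot express. And optimizing any protein is one call:

```r
p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
optimize_sequence(model, p)
#> "ATGAAAACCGCGTACATTGCGAAGCAGCGCCAG..."   # translate() gives back p
```

A shell interface wiring `simulate`, `curate`, `train`, `optimize` and
`evaluate` lives at `inst/cli/codonopt.R`:

```sh
Rscript inst/cli/codonopt.R optimize --in proteins.fasta --out opt.fasta \
    --method neural --model model.rds
```

Every run writes a JSON manifest of the parameters and seeds in effect.

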