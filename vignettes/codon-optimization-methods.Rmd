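---
title: "Context-aware codon optimization: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware codon optimization: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A protein can be encoded by an astronomical number of synonymous coding
sequences: 61 sense codons serve 20 amino acids, so most residues offer a
choice among 2–6 codons. Hosts such as *Escherichia coli* use synonymous
codons unevenly, and matching a synthetic gene to the host's usage —
codon optimization — can change heterologous expression several-fold.
The classical recipe substitutes every codon with its family's most
frequent host codon. That maximizes the Codon Adaptation Index (CAI) by
construction but ignores everything else we know about real host genes:
rare codons occur in them, and codon choice correlates with the local
sequence context, not just the genome-wide frequency table.

`codonopt` treats codon optimization as per-position sequence labeling: a
bidirectional LSTM reads the amino-acid sequence and predicts, for every
residue, a distribution over the 64 codon classes. Trained on host coding
sequences, the network reproduces the host's *contextual* codon
preferences rather than a single frequency table. Constrained decoding
then guarantees the output still encodes the input protein exactly.

## The model

Each residue is encoded either one-hot over a fixed 26-symbol alphabet
(20 standard amino acids, selenocysteine, pyrrolysine, the ambiguity
codes B/Z/X, and the stop symbol; alanine occupies feature 1) or as an
18-dimensional physicochemical descriptor vector (z-scored published
property scales covering hydropathy, polarity, volume, charge,
accessibility, secondary-structure propensity, flexibility and hydrogen
bonding). The feature sequence passes through stacked bidirectional LSTM
layers — each position's representation carries information from both the
upstream and downstream sequence — into a dense projection over the 64
codon classes and a per-position softmax.

Training minimizes per-position cross-entropy against the codons the host
actually used, with L2 regularization on the weight matrices, inverted
dropout on the recurrent layer outputs, and Adam updates over shuffled
mini-batches. Sequences are processed at full length, one at a time, with
gradients accumulated across the mini-batch; this is mathematically
identical to padded-and-masked batching and involves no padding
positions at all. The parameters with the best validation loss are
retained. Backpropagation through time is implemented in C++
(RcppArmadillo) and verified against finite-difference gradients in the
test suite.

Decoding is greedy. In the default *constrained* mode the argmax at each
position runs over the residue's synonymous family only, so
`translate(output) == input` holds identically — the mutational rate is
0.00% by construction, for any parameters, trained or not. The
*unconstrained* mode (global argmax over all 64 classes) exposes the raw
classifier behaviour and is retained precisely so that the no-mutation
property is measurable rather than assumed. Ties break to the
lexicographically smaller codon everywhere, making every decode
deterministic.

### Hyperparameters

The default profile is 2 stacked bidirectional layers × 256 units per
direction, dropout 0.2, L2 1e-4, learning rate 1e-3, batch 32, 50
epochs — a configuration family appropriate for corpora of thousands of
host genes. `test_profile()` (1 layer × 64 units, 10 epochs, batch 16,
learning rate 5e-3) is used throughout the test suite and the worked
examples; the higher step size compensates for the far smaller number of
Adam steps such runs take. All randomness — initialization, shuffling,
dropout — derives from the single `seed` field of the configuration.

## Baselines

Four frequency-based optimizers provide the comparison points:

* **URC** (uniform random choice): each position draws uniformly from its
  synonymous family.
* **BFC** (background frequency choice): draws follow the host's
  within-family frequencies.
* **HFC** (highest frequency choice): deterministic most-frequent-codon
  substitution; its CAI against the same table is exactly 1.0, which the
  test suite asserts for arbitrary random tables.
* **ERC** (extended random choice): k URC candidates scored by CAI, best
  kept — a sampled stand-in for exhaustive single-metric search. k
  defaults to 10,000 for the standalone function; evaluation runs use
  k = 100. With k far exceeding a short protein's number of synonymous
  combinations, ERC provably finds the global CAI optimum (checked
  against exhaustive enumeration).

## The evaluation suite

* **CAI** — Sharp–Li geometric mean of relative adaptiveness
  `w(c) = f(c) / max f within family`, excluding stop codons and
  single-codon families (ATG, TGG); zero-usage codons in otherwise
  observed families are floored at `w = 1e-4`. Families with no observed
  usage get `NA` weights, and an error is raised only if such a family is
  actually scored — tables tallied from small gene sets routinely lack
  some families, and erroring at construction would make CAI ranking
  unusable on its own inputs.
* **GC-content** — global G+C percentage; the conventional acceptability
  band for synthetic genes is 30–70%.
* **CFD** — percentage of codons with `w < 0.30` (strict), the usual
  rare-codon cutoff.
* **Negative repeat elements** — distinct maximal repeated substrings of
  length ≥ 10 on the direct strand (occurrences may overlap; maximality
  means not contained in a longer repeated substring). Verified against a
  brute-force substring tally.
* **Negative cis-regulatory elements** — total motif matches on both
  strands, overlaps counted, for a configurable IUPAC motif list
  defaulting to internal Shine–Dalgarno cores (AGGAGG, GGAGG), the
  sigma-70 −10 box (TATAAT), the chi site (GCTGGTGG) and A8/T8
  homopolymers. Commercial rare-codon analyzers use proprietary,
  unpublished element lists, so absolute counts from this transparent
  substitute are not comparable to theirs; only relational comparisons
  between methods run through the same counter are meaningful.
* **Mutational rate** — percentage of amino acids changed after
  back-translation of the optimized sequence.

`evaluate()` applies all metrics to every method × sequence combination
and reports two-sample t-tests on CAI and two-sided Mann–Whitney U tests
on the repeat and cis-element counts against a reference method,
mirroring the test choices conventional in this literature.

## Dataset curation

The curation pipeline reproduces the standard recipe for building a
high-expression host training set: drop proteins shorter than 90 residues
(such genes are typically hypothetical or specialized), remove redundancy
above 90% nucleotide identity, rank by CAI and keep the top N, then split
70/10/20 into train/validation/test.

Redundancy removal is a greedy CD-HIT-style pass written in R: sort by
length descending, join the first representative exceeding the identity
threshold (best ungapped k-mer-anchored diagonal, matches divided by the
shorter length — the CD-HIT denominator convention), otherwise found a
new cluster. Shelling out to the CD-HIT binary would add a dependency
without changing what the step does; the greedy implementation is instead
held to a brute-force all-diagonal oracle in the tests.

Split sizes use nearest-integer rounding for the validation and test
fractions with the remainder to train — the only convention under which
fractions 0.7/0.1/0.2 of 7,406 genes give exactly 5,184/741/1,481, the
canonical partition this pipeline is expected to reproduce. Whether the
original partition was random or CAI-ordered is not documented anywhere;
this implementation shuffles under a recorded seed, which the curation
log makes auditable.

## The synthetic host generator

Training on real genomes is supported (FASTA in, usage tables out), but
every claim in the test suite is exercised on synthetic hosts so the
ground truth is known exactly. A `synthetic_host` holds, per synonymous
family, either one codon distribution (context order 0) or one per
previous amino acid plus a start context (order 1). Distributions are
Dirichlet draws with concentration `2(1−b)/b` for bias strength `b`:
`b → 1` approaches deterministic per-context choice, `b → 0` uniform
choice; `b = 1` exactly yields point masses. Order-1 hosts are redrawn
until some family's conditionals differ across contexts by total
variation > 0.2, so "context matters" is guaranteed, not hoped for.
Amino acids are drawn i.i.d. from a fixed *E. coli*-like proteome-average
composition shipped as package data.

The central property this enables: the best possible per-position
accuracy of *any* frequency-only predictor is analytically computable
(`accuracy_ceilings()`), as is the Bayes-optimal context-aware ceiling.
On order-1 hosts the trained network must land strictly between the two;
on order-0 hosts it must match the (single) ceiling within sampling
noise. That is the desk-scale embodiment of the claim that recurrent
context yields codon selection closer to the host genome than frequency
methods can achieve — and it is a parameter-recovery test, not a
benchmark score.

What the generator deliberately does not emulate: GC-skew gradients,
operon structure, mRNA secondary structure, amino-acid autocorrelation,
and context beyond the immediately preceding residue. Passing tests
therefore demonstrate correct machinery and recoverable context signal,
not expression gains in living cells.

`make_benchmark_fixture()` produces a 40-gene evaluation set shaped like
the published heterologous-expression benchmark (mean length about
562 amino acids ≈ 1688 nt), sampled from a deliberately low-bias host so
every optimizer has headroom. The real benchmark's published summary
properties (e.g. mean degeneracy 2.91 codons/residue) reflect its
particular protein composition and are not forced onto the fixture.

## Numerical and interface choices

* Codon label space is all 64 codons, indexed lexicographically
  (AAA = 1 … TTT = 64); constrained decoding masks illegal classes rather
  than shrinking the head.
* Usage tables are two-column `codon value` text (Kazusa-style); values
  summing to ≈1000 are recognized as per-thousand frequencies, anything
  else as counts; frequencies are renormalized either way. Stop codons
  are excluded from usage (CAI and CFD are defined over sense codons).
* The bundled default table `ecoli_like_usage_synthetic.tsv` is a
  hand-written approximation of *E. coli* K-12 usage for out-of-the-box
  defaults, labelled synthetic; real design work should supply a measured
  table, and every function accepts one.
* A terminal stop codon on an input CDS is preserved verbatim by the CLI
  optimizers; internal stops are rejected.
* U→T and case normalization happen at every boundary; IUPAC ambiguity
  in sequences is rejected (motifs may use it).
* Model archives are versioned RDS containers (weights, config, alphabet,
  history); a loaded model predicts bit-identically. Export to an
  exchange format such as ONNX is not implemented — no writer for it
  exists in this R stack — and is noted as a limitation.
* The problem sizes used by the tests and the acceptance script — 300
  training genes of 90–200 (tests) or 90–600 (acceptance) residues,
  test-profile training, 40–50 held-out genes — were chosen as the
  smallest sizes at which the context-recovery margin is comfortably
  larger than its sampling noise.

## Known limitations

The model family is reproduced, not any particular released weight set;
published headline numbers that depend on a specific GenBank snapshot, an
unpublished CAI reference table, or a proprietary comparison service are
out of reach by construction. CAI values are only comparable within a
fixed usage table. The repeat and cis-element counters are transparent
substitutes for unpublished commercial definitions. Training at the
full-corpus scale (thousands of genes × 50 epochs) is supported by the
same code paths but is a workstation job, not a unit-test job.
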