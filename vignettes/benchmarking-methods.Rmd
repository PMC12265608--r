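---
title: "Biologically-aware benchmarking of transcript representations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biologically-aware benchmarking of transcript representations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txbench)
```

txbench implements the evaluation machinery used to benchmark predictors of
mature-mRNA properties: how to split data so that scores measure
generalization rather than memorization, how to quantify the distributional
differences between genomic regions that drive cross-region transfer
failures, how to probe frozen sequence embeddings fairly, how to aggregate
heterogeneous metrics across datasets, and how to test compositional
generalization over known regulatory elements. Everything runs on synthetic
transcripts built by the package's own generators, so every analysis is
reproducible from a seed with no external data.

This vignette records the scientific and numerical decisions behind each
component — what is modelled, which parameters matter, and where the design
was genuinely open.

## Transcripts and the six-track encoding

A transcript is the spliced, exon-only mRNA in 5'→3' orientation, with
0-based, half-open transcript-relative coordinates. Half-open intervals are
closed under the chunking and concatenation arithmetic used throughout, and
one canonical alphabet ({A,C,G,T,N}, U accepted on input) keeps all k-mer
logic single-cased.

`six_track_encode()` produces the 6 × L input used by splice-aware models:
four one-hot base rows, a *splice track* and a *codon track*. The splice
track marks the first nucleotide of each exon and the codon track the first
nucleotide of each codon within the CDS. Annotation toolkits differ in
whether they mark donor sites, acceptor sites, or both; we chose the
first-nucleotide-of-exon convention because it is defined purely by the
transcript-relative annotation carried on the record, making it exactly
testable without a genome. This is a deliberate simplification and is
flagged as such.

`chunk_sequence()` defaults to zero overlap: transcript embeddings are
means over positions, and overlapping chunks would silently double-count
the overlapped bases in the pooled mean (`pool_embeddings()` weights chunk
means by chunk length, which is exact only for a partition).

## Data splitting and leakage

Random splits overestimate generalization whenever related sequences land
on both sides. Three strategies control specific leakage channels:

* **Chromosomal holdout** (`chromosome_split()`) — the conventional
  genomics split; coarse, and still leaky through inter-chromosomal
  homology.
* **K-mer clustering** (`kmer_cluster_split()`) — sequences are
  represented by row-normalized overlapping k-mer frequencies and
  clustered with k-means; whole clusters go to one side. Defaults: k = 5
  (mid-range of typical RBP motif lengths, 4–7 nt) and
  `n_clusters = max(10, n/50)` — coarse enough that motif-sharing
  sequences co-cluster, fine enough that greedy assignment can approach
  the target test fraction. Both are configurable; neither is canonical.
* **Homology grouping** (`homology_split()`) — paralog edges below a 35%
  identity threshold are discarded as low-confidence, the surviving graph
  is closed transitively (`transitive_groups()`), and connected components
  move as units. Split granularity is the *gene*: all isoforms travel
  together, since intra-gene redundancy is the most direct leak.

Clusters/groups are assigned to the test side greedily, largest first,
with ties broken in seeded random order, until the requested fraction is
first reached. The achieved test fraction therefore deviates from the
target by at most the largest group size; the greedy rule is deterministic
under the seed, and with singleton groups it degenerates to a
size-constrained random split. Positional identity
(`pairwise_identity()`) is intentionally alignment-free: equal-length
synthetic paralogs are compared per site, and real paralog tables carry
their own precomputed identity column.

`leakage_report()` quantifies what a split leaves open: paralog pairs
crossing the boundary and the fraction of test-side k-mers also present in
train.

## Region grammars and Huffman compressibility

Compressed code length under an optimal prefix code approximates the
entropy of the token distribution, so region-specific Huffman grammars
expose how much statistical structure a genomic region carries and how far
two regions' distributions diverge.

Numerical decisions:

* **Token unit.** Tokens are non-overlapping k-nucleotide blocks,
  default k = 3. Single-nucleotide tokens cannot code below 2 bits/nt on
  near-uniform base compositions (the Huffman code over a 4-symbol
  near-uniform alphabet is flat), so codon-scale structure — the very
  signal that makes coding sequence compressible — is invisible at k = 1.
  Codon-width blocks make it the dominant term.
* **Pseudo-counts.** Every one of the 4^k tokens receives
  `pseudo_count = 1` by default, so any grammar can encode any corpus and
  cross-compression is always defined. With `pseudo_count = 0` an unseen
  token is a hard error rather than a silent escape mechanism that would
  change code lengths unaccountably.
* **Baseline.** Ratios are coded bits over 2 bits per nucleotide — the
  trivial fixed-length encoding.
* **Determinism.** Ties in the Huffman merge queue are broken by the
  lexicographically smallest token in each subtree, so identical corpora
  give byte-identical codebooks.
* Reported values are realized bit counts of the actual corpus, not
  analytic expectations.

The cross-compression matrix reports, for each (source grammar, target
corpus) pair, the percent increase over the target's self-compression
ratio — zero on the diagonal, and non-negative off it up to sampling error
(cross-entropy is bounded below by entropy). The tests verify the Huffman
construction against an exhaustive optimal-prefix-tree oracle, Kraft
equality, the `H ≤ E[len] < H+1` sandwich with dyadic distributions
meeting `H` exactly, and the Gibbs direction on simulated Markov corpora.
Printed ratios from genome-scale corpora are not reproducible here — they
depend on the corpus — but every qualitative relation is.

## Linear probing

`fit_and_score_probe()` trains a linear model on frozen embeddings:
ridge regression (closed form) scored by Pearson r for regression tasks, a
ridge-penalized logistic model scored by AUPRC for binary tasks, and
one-vs-rest with unweighted mean AUPRC for multilabel tasks (test columns
with one class are excluded, with a warning). The probe family and penalty
strength (default 1.0) are conventional choices — convex, deterministic,
and configurable — not canonical values. AUPRC is average precision, the
step-wise integral of the precision–recall curve, with tied scores moved
across the threshold as a block; it is verified against a rank-based
oracle in the tests.

Feature standardization uses training statistics only. This is assertable,
not just asserted: probe predictions are returned label-free, and the
tests check they are bit-identical under permutation of test labels.

`run_benchmark_protocol()` repeats split–fit–score over ten random seeds
by default and reports per-subtask means with standard errors over the
seeds that scored successfully.

## Cross-dataset aggregation

Subtask and seed scores are mean-aggregated to one value per (model,
dataset); Pearson metrics pass through the Fisher transform (`atanh`)
first, since raw correlations compress near ±1 and average badly. Within
each dataset, model scores are Z-scored using the sample (n−1) standard
deviation — model counts per dataset are small — and a model's overall
score is its unweighted mean Z across the datasets it covers. Missing
(model, dataset) cells are dropped and counted, never imputed. The
global-vs-local bias statistic is the difference of mean Z between the two
locality classes; it is antisymmetric under swapping the class labels.

`compare_models()` wraps the two-sided Wilcoxon signed-rank test for
paired scores (exact distribution for n ≤ 25 when |differences| are
tie-free, tie-corrected normal approximation otherwise) and Welch's
unequal-variance t-test for independent groups. The tests verify the
exact path against full sign-assignment enumeration and the Welch type-I
error at the nominal 0.05 over 2000 null replicates.

## Compositional generalization over uAUG × Kozak

The design holds out one combination of two regulatory elements of the
5'UTR: upstream AUGs (suppress ribosome load) and Kozak context strength
(enhances it). Training covers (strong, no-uAUG), (weak, no-uAUG) and
(strong, uAUG); the test set is exactly the never-seen (weak, uAUG) cell.

Two modelling choices were open:

* **Kozak binarization.** Strong iff purine at −3 *and* G at +4 — the two
  consensus positions with the largest measured effect on initiation. Real
  MPRA studies score context continuously; a two-position rule is the
  simplest faithful binarization and is applied identically by the
  generator and the annotator.
* **uAUG detection.** Any ATG in the provided UTR counts, in any frame,
  with no requirement for a downstream in-frame stop (no uORF/uAUG
  distinction).

The synthetic MPRA generator (`simulate_mpra_utrs()`) models ribosome
load as `y = β0 + βk·s − βu·c + γ·s·c + ε`. In binary mode `s` and `c` are
the cell indicators and the formula is exact per cell. Binary mode,
however, makes labels constant within a cell, and the compositional test
set *is* a single cell — Pearson r on it is undefined. Real MPRA libraries
vary continuously within cells, so the generator's graded mode draws a
continuous Kozak score (strong `s ∈ [0.7, 1]`, weak `s ∈ [0, 0.3]`) and a
planted uAUG count `c ∈ {1, 2, 3}`, restoring within-cell label variance.
All compositional-transfer analyses use graded mode.

With γ = 0 the label is additive and a linear probe on (s, c) extrapolates
to the held-out cell almost perfectly — the additive case is
compositionally solvable, and the tests require r > 0.95 there. The sign
of a large interaction matters: with γ < 0 (synergistic suppression) the
probe's learned uAUG slope stays sign-correct in the held-out cell and the
drop versus random splitting is small, whereas γ > 0 — strong Kozak
*rescuing* uAUG suppression — loads the interaction onto the uAUG slope in
the only training cell that has uAUGs, so the learned slope is badly wrong
exactly where the test cell needs it. The interaction benchmark therefore
uses γ = +4 against main effects of 1–2, and the drop exceeds 25% by a
wide margin.

## Reference objectives and the mixing demonstration

`mlm_loss()`, `dcl_loss()` and `scalarized_loss()` are exact, desk-scale
reference implementations. The decoupled contrastive loss excludes both
views of the anchor sample from the normalizing sum and is anchored on
view 1 as printed in its source method; a symmetric variant (averaging
both anchorings) sits behind a flag, off by default. The per-sample
positive weights default to 1 — the weighting form is inherited from the
cited method without a printed definition, so the unweighted case is the
reference. Batch reduction is the mean. `dcl_loss()` is verified against
a literal brute-force double sum to 1e−10.

`sweep_objective_mix()` demonstrates, at toy scale, why mixing the two
objectives matters for global tasks. Sequences come from paralog families;
the global label is a hidden per-family value. The encoder is a 16→d
(`d = 4`) tanh bottleneck over dinucleotide frequencies; its MLM head
predicts masked bases from the sequence embedding, and its contrastive
views pair each sequence with a *family sibling* — the orthology-style
augmentation of the method the loss comes from. Composition statistics
(all the MLM head rewards) separate families poorly, while the
contrastive term makes family identity linearly decodable, so the probed
global score improves as soon as α < 1. Three details keep this
demonstration honest rather than lucky: a weight-decay term (default
0.05) shrinks representation directions the objective does not reward —
otherwise accidental family signal survives from the random
initialization of an MLM-only encoder; scores are averaged over three
encoder initializations (the toy optimization is non-convex); and over
three probe splits. What this toy shows is the *mechanism*; it says
nothing about the scale-dependent behaviour of real pre-training.

## What the generators emulate — and what they do not

* `simulate_markov_region()` / `simulate_cds_region()` reproduce
  low-order composition differences between genomic regions (order-0/1
  Markov structure; i.i.d. codon usage). They contain no long-range
  structure, no splice signals, no secondary-structure constraints.
* `simulate_paralog_families()` uses i.i.d. per-site substitution (to a
  uniformly chosen different base, probability `1 − target_identity` per
  member against the ancestor) with no indels, so positional identity is
  exact and two members of a family match per site with probability
  `(1−μ)² + μ²/3` — the tests assert against this counting oracle rather
  than against the nominal target.
* `simulate_motif_labels()` plants literal motifs; real RBP binding is
  degenerate and context-dependent.
* `simulate_mpra_utrs()` guarantees its design cells exactly (no ATG
  anywhere in uAUG-free UTRs; planted ATGs clear of the Kozak window) —
  cleaner than any real library.

Passing tests on these corpora demonstrate that the *evaluation machinery*
behaves as specified (splits leak or don't, compression orders regions
correctly, probes don't touch test data), not that any conclusion
transfers to a particular real dataset.

## Problem sizes and determinism

The shipped tests and the acceptance script size their simulations to
desk scale as the package's own study conditions: 500–1000 random
distributions for the coding-theory checks, 200 random graphs for the
grouping oracle, 180-sequence motif corpora over 10 split seeds, 160
MPRA constructs per replicate over 10 seeds, 2000 null replicates for test
calibration, and a 72-sequence family corpus for the objective sweep.
Every stochastic component takes an explicit integer seed;
`derive_seed()` hashes a stage name against the run seed so pipeline
stages are reproducible in isolation, and identical configs yield
byte-identical outputs (asserted in the tests).

## Known limitations

* Identity is positional; unequal-length homology requires an external
  edge list.
* The six-track splice convention is one of several defensible choices.
* The Huffman analysis measures block-entropy structure only; it is not
  a general-purpose compressor and will not see structure at ranges
  beyond k.
* The multilabel AUPRC average is unweighted; datasets whose labels have
  very different prevalences weight rare labels up.
* The toy encoder is a mechanism demonstration, not a miniature of any
  production architecture (no Mamba/transformer backbone, no token-level
  context in the MLM head).
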