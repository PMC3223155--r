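---
title: "Markov-model classification of metagenomic reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-model classification of metagenomic reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovbin)
```

## The model

`markovbin` assigns a read to a source genome by comparing the read's
short-range composition with a fixed-order Markov model of each
reference genome. A state of the order-*k* model is a *k*-mer; the next
state shares *k*−1 bases with it, so one transition is fully described
by a (*k*+1)-mer — the *context* (first *k* bases) plus the *successor*
base — and there are 4^(k+1) transitions in total. Training tallies
every (*k*+1)-mer window of every replicon of a genome; the transition
probability is the window count divided by the context's total outgoing
count, and what is stored is its negative natural logarithm, a
non-negative *cost*. A read of length *l* is *l*−*k* consecutive
transitions, and its score against a genome is the sum of their costs;
transitions the genome never exhibited contribute a constant
`missing_cost` each. The genome with the minimum score wins, and the
read inherits that genome's seven-rank lineage
(superkingdom…species).

Because every genome is a vector of fixed length 4^(k+1), scoring a
batch of reads against all genomes is a single dense matrix product of
the read-by-transition count matrix with the transposed genome-by-
transition cost matrix. That uniform representation is the point of the
design: per-read work scales as 4^(k+1)·N for N genomes, it
parallelizes trivially, and the same product can be handed to any BLAS
or GPU GEMM. The package ships a `vectorized` backend (R's BLAS-backed
`%*%`), a deliberately naive `reference` backend that accumulates each
read's transitions one at a time and exists as an in-package oracle for
the product, and accepts `accelerated` as an alias of the dense path so
callers can write backend-agnostic code.

Model assumptions worth stating: reads are treated as i.i.d. samples of
their source genome's transition process (no positional or coding-frame
structure); scores of different genomes are comparable because every
read contributes the same number of transitions to each row; and an
unseen transition is evidence *against* a genome of fixed strength
rather than something to smooth over — there are no pseudocounts, which
keeps the penalty rule exact and the model faithful to its training
counts.

## Counting conventions and degenerate inputs

* A window containing any non-ACGT symbol is skipped; neighbouring
  windows are unaffected. Counting is case-insensitive.
* The context total F(context) is the *row sum of outgoing transitions*,
  not the raw k-mer occurrence count. The two differ only at sequence
  ends (a terminal k-mer has no successor); the row-sum definition makes
  each context's observed probabilities sum to exactly 1, which the test
  suite asserts to 1e−9.
* The transition-probability notation is read as the standard
  conditional P(successor | context) — probability of moving *from* the
  context k-mer *to* the k-mer that appends the successor base.
* All replicons (chromosomes and plasmids) of one genome feed a single
  model.
* Under the default `strand_policy = "both"`, each replicon's reverse
  complement is counted too, so classification is orientation-invariant
  and reverse-strand reads need no special handling. `"forward"` is
  available for strictly single-stranded use; with forward models a
  caller can classify both orientations of a read and keep the smaller
  score.
* A sequence shorter than *k*+2 bases yields zero transitions. For a
  training genome that is an error (an all-missing model is refused);
  for a query read it is not — the read is reported with the sentinel
  genome id `UNCLASSIFIED` so one bad read never aborts a run.
  Accuracy computations count unclassified reads in the denominator
  (as wrong), so accuracies stay comparable across settings.
* Ties in the argmin are broken toward the lowest database row index,
  deterministically.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 5 | bases of context | Accuracy improves with k only while 4^(k+1) stays well below the training-genome length; past that, unseen-transition penalties dominate and compute grows 4× per increment. Order 5 (4096 cells) is a good operating point for typical bacterial genomes (megabases). Range 1–8; 8 is capped for memory (4^9 cells/genome). |
| `missing_cost` | 10 | −log probability (nats) | Charged per transition absent from a genome's training counts. 10 nats ≈ probability 4.5e−5, far below any observed transition of a megabase genome, so a handful of unseen transitions outweighs many well-fitting ones without saturating the score. |
| `strand_policy` | `"both"` | — | Orientation-invariant models by construction (see above). |
| `batch_size` | 1024 | reads | Bounds the read-count and score matrices at batch_size × 4^(k+1) cells; results are provably identical for every batch size (batching is a pure partition of the read set). |
| `backend` | `"vectorized"` | — | BLAS product; `reference` is the per-transition oracle, `accelerated` an alias of the dense path. |

## Numerical choices

Logarithms are natural; the missing cost default of 10 is in the same
−log units. Genome models built by `build_model()` keep their costs in
double precision, so per-context probabilities recovered by
`exp(−cost)` normalize to 1 within 1e−9. When models are stacked into a
reference database the rows are quantized to IEEE-754 binary32 — the
precision of the on-disk container (little-endian float32, row-major)
and of single-precision GEMM — so `load(save(db))` reproduces the
matrix bit-exactly and incremental extension (`add_genome`) is
bit-identical to a from-scratch rebuild. Binary32 quantization perturbs
a cost by at most ~6e−8 relative, invisible at the 1e−4 score tolerance
the backends are held to. Score accumulation is always in double
precision regardless of the stored width, which stabilizes the argmin;
with the standard fixture the gap between best and second-best genome
is orders of magnitude above the float tolerance, so assignments are
identical across batch sizes and backends.

## The synthetic benchmark

Real reference collections are large and external, so the package
carries its own fixture generator. `simulate_genome()` draws each
transition row of an order-`order` chain from a symmetric
Dirichlet(`concentration`) and walks the chain; small concentrations
yield sharply peaked rows, hence compositionally well-separated
genomes. `make_benchmark()` assembles the standard study conditions
used throughout the tests: **20 genomes of 100 kb** (order-3 chains,
concentration 0.1), a synthetic lineage (one genus/species per genome,
genera grouped round-robin into 5 phyla so every rank carries signal),
and **50 error-free reads per genome at 100, 500 and 1000 bp**, all
derived from one master seed (42 in the shipped tests). The generator
order (3) deliberately differs from the classifier order (5): recovery
must not depend on a model-order match. Reads are sampled uniformly in
position and strand; an optional i.i.d. substitution rate exists for
robustness experiments and defaults to 0.

On this fixture, classifying the reads back against a database built
from the very same genomes recovers ≥ 95% of 500 bp and 1000 bp reads
at genome level, and accuracy at 1000 bp is at least that at 100 bp —
the qualitative length trend expected of composition methods, which the
test suite asserts. What passing these tests shows is that the
training, vectorization, scoring and bookkeeping machinery is correct
and self-consistent. What it does *not* show is real-world accuracy:
synthetic chain genomes have no repeats, mobile elements, GC skew,
conserved genes shared across taxa, or sequencing-error structure
(no homopolymer indels, no quality-dependent substitutions), and the
self-recovery design sidesteps the hard case of classifying reads whose
source genome is absent from the database. Expect substantially lower
rank-level accuracy on real metagenomes, degrading with read length and
evolutionary distance to the references.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the standard 20-genome /
100 kb / 3 × 1000-read fixture for end-to-end checks, 10-genome ×
50-read sweeps at k ∈ {1,2,3,5} for backend-vs-oracle agreement, and
20 random 3 kb genomes at k ∈ {1,3,5} for normalization — sizes chosen
so the whole suite exercises every path in well under a minute on one
core while keeping the statistical assertions (binomial bands,
accuracy thresholds) far from their noise floors.

## Known limitations

* Fixed-order models only: no interpolated or variable-order smoothing,
  no pseudocounts, and no confidence score attached to an assignment —
  the score gap between the best and second-best genome is reported
  only implicitly via `top = N`.
* The seven-rank lineage schema is fixed; intermediate "no rank" nodes
  of real taxonomies must be projected onto it upstream.
* `read_fasta()` parses eagerly (streaming laziness is delegated to
  batching, which bounds the large matrices); FASTQ input and quality
  values are not handled.
* One CPU code path; the `accelerated` backend name is a contract for
  plugging in GPU/BLAS variants, all of which must pass the same
  equivalence suite, not a shipped GPU implementation.
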