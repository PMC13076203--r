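---
title: "Cascaded protein clustering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded protein clustering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascclust)
```

## The clustering model

`cascclust` computes a *representative-based* clustering: a subset of
representative sequences such that every input sequence lies within a
user-defined alignment distance of its representative. The distance is the
**clustering criterion**, checked on an optimal local alignment of the
pair:

* e-value at most `max_evalue` (default 0.001), computed as
  `E = K·m·n·exp(−λS)` with `m` the query length and `n` the residue count
  of the current representative set;
* sequence identity at least `min_id` — identical aligned residue pairs
  divided by all alignment columns, gap columns included. Setting
  `min_id = 0` is *deep clustering*: only alignment significance and
  coverage connect remote homologs;
* coverage at least `min_cov` of the member sequence (`cov_mode = "uni"`)
  or of both sequences (`cov_mode = "bi"`). Coverage of a side is the
  aligned span length divided by the sequence length.

Alignments passing the criterion are encoded as a directed graph (A→B: "A
can represent B"; in bi mode edges come in symmetric pairs, in uni mode the
directions are checked separately). Representatives are extracted by
**greedy vertex cover**: repeatedly take the live node of maximal live
outdegree and absorb every live node reachable within `depth` directed hops.
Depth 1 absorbs direct out-neighbors; unbounded depth would reproduce the
weakly connected components (`connected_components()`).

### Assumptions

The model assumes that pairwise local alignment similarity is an adequate
proxy for homology at the thresholds used, and that a cluster is well
summarized by a single representative within criterion distance of each
member. It does not detect weak edges between densely connected communities
(no Markov-style graph refinement), and its sensitivity is bounded by what
pairwise (not profile) alignment can detect.

## The cascade

An exhaustive all-vs-all comparison is quadratic, so clustering proceeds in
2–6 **rounds** over a shrinking representative set at increasing alignment
sensitivity (`faster`, `fast`, `default`, `sensitive`, `very-sensitive`,
`ultra-sensitive`):

1. round 1: linear stage with minimizer subsampling (window 12), vertex
   cover at depth 1;
2. round 2: linear stage on all seeds, depth 1;
3. rounds 3+: all-vs-all at escalating sensitivity, depth 3.

Early rounds use a **more stringent criterion** that later rounds relax:
every round up to and including default sensitivity adds +7 percentage
points to the identity and coverage thresholds; the sensitive round adds +5
points to coverage only; later rounds use the base criterion. Thresholds
are clamped at 1. With a 20% base identity cutoff, rounds up to default
therefore run at 27%:

```{r}
base <- cluster_criterion(min_id = 0.20, min_cov = 0.80)
round_criterion(base, round_spec("default"))$min_id
```

Because representatives only shrink and each round's assignment is composed
onto the previous ones, the final result is a partition of the input in
which each member connects to its representative through a short chain of
criterion-passing alignments (the per-round clusterings are kept in the
`history` attribute so this chain can be re-verified, as the test suite
does).

### The modeled sensitivity ladder

The sensitivity levels of the underlying aligner are engine internals not
specified at the algorithmic level, so this package models them explicitly
as seed-shape sets used for candidate generation: one contiguous weight-7
shape for `faster`/`fast` (round 1 additionally subsamples with
minimizers), four weight-6 spaced shapes for `default`, eight weight-5
shapes for `sensitive`, twelve weight-4 shapes for `very-sensitive`, and
seedless evaluation of every length-compatible pair for `ultra-sensitive`.
The mapping is a deliberate, documented approximation: what matters for
the method's guarantees (and what the tests check) is that candidate
generation is sound — edges are only ever a subset of what exhaustive
comparison plus the criterion would accept — and that sensitivity grows
along the ladder.

## Linear-stage candidate generation

Sequences sharing an identical seed key are grouped, and only selected
pairs within a group are aligned:

* **uni mode**: every member against the longest group member — under
  uni-directional coverage the longest sequence is a priori the best
  recruiter.
* **bi mode**: the group is sorted by decreasing length and swept with an
  interval `[i; j]` in which all lengths are within ratio `c + δ` of the
  interval head; interval members are aligned against the member at the
  median index `⌊(i+j)/2⌋`, then the interval advances. The sweep never
  emits a pair whose lengths alone rule out bi-directional coverage `c`.

The justification is the **length-ratio property**: a local alignment can
cover fraction `c` of both sequences only if the shorter/longer length
ratio exceeds roughly `c` (up to a gap allowance). The linear stage applies
it stringently (`+δ`, default 0.05, which *reduces* candidate pairs), while
all-vs-all rounds under a bi criterion apply it permissively (`−ε`, default
0.05) to prune pairs before alignment without losing any edge — the test
suite verifies the pruned edge set equals the exhaustive one exactly on 500
synthetic sequences.

One printed formulation of the interval-advance rule is ambiguous about the
direction of the length ratio; this package advances `i` to the first index
whose length is within shorter/longer ratio `c + δ` of the next sequence
`l_{j+1}`, the reading under which the sweep makes progress and the
stringent filter is meaningful.

## Seeds, minimizers and learned shapes

Seed keys are a deterministic multiply-mix hash of the residues at a
shape's care positions, truncated to 53 bits so keys are exactly
representable as R doubles (fixed constants; identical across platforms and
runs). Minimizer subsampling keeps, for every window of `w = 12`
consecutive seed positions, the seed of minimal key (leftmost on ties,
duplicates merged), so the sample size scales with sequence length; a
sequence long enough to carry a seed but shorter than `span + w − 1` emits
its single minimal seed so every sequence stays seedable. No reduced
amino-acid alphabet is applied before hashing; this is a documented
difference from engines that compress the alphabet at the seeding stage.

For the pure linear mode (`linclust()`), the third round uses 30 spaced
shapes of weight 10 (depth-2 clustering), replacing all-vs-all stages
entirely. `learn_shapes()` can design such shape sets empirically from a
collection of column-level alignments by greedy set cover: pick the shape
hitting the most remaining alignments, drop what it hits, repeat. For small
spaces (weight ≤ 5, span ≤ 10) the candidate search is exhaustive — the
first pick provably matches full enumeration — otherwise hill climbing from
the contiguous shape with seeded random restarts is used, since the space
of weight-10 patterns is too large to enumerate. The built-in default set
is a deterministic stride through the weight-10 pattern space (contiguous
shape first), chosen once rather than learned, so that linear mode needs no
training input.

## Evaluation metrics

Given per-sequence domain architectures (ordered family-label tuples) and
an optional family→clan map:

* sensitivity of an annotated sequence = same-architecture sequences in its
  cluster / same-architecture sequences in the input;
* precision = clan-equivalent annotated sequences in its cluster /
  annotated sequences in its cluster. Clan equivalence is positional: equal
  architecture length, k-th families identical or sharing a clan.

Both are averaged arithmetically over annotated sequences; non-annotated
sequences are ignored everywhere, including the precision denominator —
the printed formula ("divided by the size of the cluster") is ambiguous on
this point, and ignoring unannotated members is the reading consistent
with evaluating only the annotated subset. Architecture repeats are
preserved and order matters; these conventions are fixed choices where the
metric's verbal definition is silent.

## The synthetic-family generator

`simulate_families()` emulates the structure the method is designed to
recover: per family a random root drawn from fixed background amino-acid
frequencies (a standard composition table embedded as constants), members
mutated to a target co-linear identity (substitutions always change the
residue, so realized identity is exact before indels), optional short
indels (Poisson events, geometric lengths), optional terminal truncations
that bound attainable coverage at ~`1 − fraction`, plus unrelated
background singletons. Defaults — 20 families of 10 members at 85–95%
identity to the root, no truncation, indel rate 0.005, 50 singletons —
are the reference condition used throughout the tests: at these settings
cascaded clustering at `min_id = 0.3`, bi coverage 0.8 recovers the family
partition with adjusted Rand index ≥ 0.95.

What the generator does *not* emulate: substitution-matrix-biased mutation,
rate heterogeneity along sequences, phylogenetic (tree-shaped) divergence
within families, compositional bias, and real multi-domain shuffling.
Passing the recovery tests therefore demonstrates the machinery is correct
and calibrated on idealized families, not that the thresholds are optimal
for any particular real database.

## Numerical choices and degenerate inputs

* Alignment: scalar affine-gap Smith–Waterman (gap of length L costs
  `gap_open + L·gap_ext`, default 11/1, BLOSUM62); scores verified
  exhaustively against an independent full-DP implementation. Score-0
  alignments return empty spans and coverage 0. Traceback prefers diagonal
  moves on score ties.
* Ambiguity codes (X, B, Z, U, O) score by their matrix rows where defined
  (0 otherwise) and never count as identities; letters outside the
  25-letter alphabet are replaced by X with a warning on input.
* Karlin–Altschul constants λ = 0.267, K = 0.041 (standard gapped BLOSUM62
  11/1 values); `n` is the total residue count of the current
  representative set. For a directed edge evaluated in the reverse
  direction of a stored hit, the hit's e-value is reused rather than
  recomputed with swapped roles.
* Greedy vertex cover ties: higher outdegree, then longer sequence, then
  lexicographically smaller id — fixed so results are reproducible.
  Outdegrees are maintained over live nodes only.
* Deduplication keeps the first-seen record of identical residue strings.
  Cluster TSVs are written sorted (representative, then member) so outputs
  are byte-stable; the determinism test runs the whole
  simulate→cluster→evaluate pipeline twice and compares bytes.
* Interval sweep and length filters use `min/max length ratio ≥ c + tol`
  with signed `tol` unifying the stringent (+δ) and permissive (−ε) uses.

## Problem sizes used by the test suite

The suite exercises every guarantee at deliberately desk-sized scales,
chosen to make exhaustive oracles feasible: alignment oracle equivalence on
1,000 random pairs of length ≤ 200; vertex-cover oracle equivalence on 500
random graphs of ≤ 200 nodes at depths 1–3; linear-stage soundness and
pruning losslessness on 500 synthetic sequences (124,750 exhaustive
alignments); family recovery on the 250-sequence default simulation. These
sizes are the package's reference experimental conditions.

## Known limitations

* Single-threaded, in-memory; no distributed sorting or multi-node
  execution. Intended for datasets up to a few thousand sequences.
* Sensitivity is bounded by pairwise alignment; no profile or HMM search.
* The incremental mode (`add_sequences()`) is a simplification: new
  sequences are compared to existing representatives only (best-scoring
  assignment) and the remainder is clustered independently; existing
  assignments are never revisited.
* The built-in sensitivity ladder and the built-in 30-shape set are
  modeled stand-ins for engine-specific tuning; no shape-for-shape
  equivalence with any external tool is claimed, and benchmark identity
  values of external engines are not reproduced.
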