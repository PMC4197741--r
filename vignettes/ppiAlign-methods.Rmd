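---
title: "Methods: stochastic multiple local alignment of PPI networks"
author: "ppiAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic multiple local alignment of PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiAlign)
```

## The problem

Protein-protein interaction (PPI) networks of different species often
conserve whole functional modules — ribosomal subunits, spliceosomal
cores, kinase complexes — even when sequence similarity alone would not
single them out.  *Multiple local network alignment* searches two or more
PPI networks for small subgraphs, one per network, together with a
one-to-one correspondence between their proteins, such that (i) the
mapped proteins are mutually similar (plausible orthologs) and (ii) the
subgraphs are densely and consistently wired.  Each reported alignment is
a candidate conserved complex.

`ppiAlign` implements a greedy, stochastic three-phase search for such
alignments:

1. **Bootstrap (seed) phase.**  A *seed* is one alignment row: a tuple of
   `N` proteins, one per network, drawn from the nodes of degree at least
   `sigma`.  The seed is found by Gibbs sampling: starting from a
   uniformly drawn candidate per network, the sampler cyclically
   revisits each network and resamples its member with probability
   proportional to `eps` plus the member's total similarity to the other
   `N - 1` fixed members.  The best-scoring row visited is retained and
   then polished by iterated conditional modes (each coordinate is moved
   to its conditional optimum until a fixed point), which deterministically
   repairs single-coordinate near-misses of the stochastic scan.
2. **Iterative (extension) phase.**  Each step Gibbs-samples one
   additional row from the *unused neighbours* of the current aligned
   subgraphs, with member weights `eps` + similarity to the tentative
   members + summed edge weight into the member's own column.  The step
   is kept only if it strictly increases the growth objective (below);
   otherwise it is reverted and the phase ends.
3. **Refinement phase.**  For `refine` iterations the row with the lowest
   contribution (row similarity plus intra-column connectivity) is
   removed and one replacement row is sampled as in extension.  The swap
   is kept only when the objective — growth density, with total row
   similarity as tie-break — does not decrease.

The pipeline (`alignNetworks()`) repeats seed-extend-refine for a number
of independent restarts, then discards alignments below
`minComplexSize`, deduplicates by node overlap, and sorts by size and
structural conservation.

## The growth objective, and why there are two densities

Two density notions coexist deliberately:

* `localDensity()` reports the *normalized* weighted density of the
  aligned subgraphs: per network, the sum of induced edge weights over
  `choose(k, 2)`, averaged over networks — a value in `[0, 1]`,
  comparable across alignment sizes.  It appears in result headers and
  summaries.
* The *growth objective* that extension and refinement optimise is the
  densest-subgraph-style per-row density: the sum of induced edge
  weights over `k`, averaged over networks.

The distinction matters.  The normalized density of a clique is constant
in `k`, so demanding a strict normalized-density increase at every step
would freeze any alignment whose current subgraphs are already at their
asymptotic density — greedy extension adds its best row first, making the
normalized trace non-increasing and capping alignments at two or three
rows.  The per-row density of a growing dense complex, in contrast,
increases strictly with every well-connected row and stops increasing as
soon as candidate rows connect more weakly than the current per-row
average.  It therefore supports both properties one wants from the
stopping rule: accepted-step traces are strictly increasing, and genuine
complexes are grown to their full extent.  Sparse background rows (which
would dilute the alignment) fail the acceptance test because their
connectivity falls below the current per-row average.

## Similarity model

Cross-network similarity comes in two dialects:

* **Bit scores** (`readBitScores()`): pairwise BLAST bit scores between
  proteins of different networks.  Unlisted pairs score 0.  Pairs that
  can only be placed within a single network are rejected at load time.
* **Orthology groups** (`readCogGroups()`): each protein lists its
  COG/KOG/NOG groups; the implied score of a pair is its number of
  shared groups.  This representation scales better with many networks,
  where the number of pairwise scores grows combinatorially.

The row similarity objective is the sum of pairwise scores over all
unordered network pairs of the row.  Similarity and connectivity enter
the extension weights unweighted (both raw): the two terms operate on
naturally different scales (bit scores of true orthologs are orders of
magnitude above edge weights), so similarity dominates member choice
while connectivity breaks ties among equally similar candidates — which
is the intended behaviour for recovering complexes of orthologs.

## Scoring and post-processing

**ISC (Index of Structural Conservation).**  For each unordered network
pair, the induced subgraph edges of one side are mapped through the row
correspondence onto the other; with `E_i`, `E_j` the induced edge sets
and `C_ij` their conserved intersection, the pair score is the Dice
ratio `2|C_ij| / (|E_i| + |E_j|)` (1 when both sides are edgeless, since
nothing distinguishable is unconserved), and ISC is 100 times the mean
over pairs.  Edge *presence* is counted, not weight: the index measures
topological conservation, and weights already influence what gets
aligned.  ISC is 100 exactly when every pair's induced subgraphs are
edge-identical under the mapping.

**Overlap deduplication.**  `overlapFraction()` divides the shared
(network, protein) node count by the node count of the smaller alignment
(fewer rows).  `filterByOverlap()` processes alignments by decreasing
size and keeps one only if its overlap with every kept alignment is at
most `overlap` — so of two redundant alignments the smaller dies.  The
minimum-size filter runs *before* overlap filtering: a tiny alignment
should never eliminate, nor be eliminated by reference to, complexes
that are about to be discarded anyway.

**Alignment graph.**  `buildAlignmentGraph()` merges the aligned
subgraphs into one exportable model: solid intra-edges coloured by fixed
weight bands (`p < 1/3` green, `1/3 <= p < 2/3` yellow, `p >= 2/3` red —
absolute bands, so colours are comparable across alignments) and dashed
inter-edges joining the members of each row (`choose(N, 2)` per row).
`writeGraphML()` serialises it with all attributes; layout is left to the
consumer.

## Tunable parameters

| Parameter        | Default | Meaning |
|------------------|---------|---------|
| `iterSeed`       | 200     | Gibbs iterations in the bootstrap phase; 200 suffices for up to ~25 networks |
| `iterExtend`     | 200     | Gibbs iterations per extension step |
| `sigma`          | 7       | minimum degree of seed candidates; use 1-2 for sparse networks |
| `overlap`        | 0.5     | maximum shared-node fraction of two distinct alignments |
| `refine`         | 10      | refinement iterations; higher is slower and slightly more accurate |
| `minComplexSize` | 5       | minimum rows of a reported complex |
| `seed`           | 1       | RNG seed; identical seed and inputs give byte-identical outputs |
| `restarts`       | auto    | independent seed attempts; auto = candidate seed count of the smallest network, capped at 100 |

The `restarts` policy is this package's own: the number of alignments to
attempt is otherwise unspecified, and one attempt per candidate seed of
the smallest network reproduces a full table of local alignments at
bounded cost.  A node may participate in several raw alignments; the
overlap filter, not the search, arbitrates redundancy.

## Numerical choices

* Gibbs conditionals use an additive floor `eps = 1e-6`, so zero-similarity
  candidates remain reachable and every conditional is well defined.
* Networks are scanned cyclically (round-robin), a standard deterministic
  Gibbs schedule.
* Extension acceptance demands a *strict* objective increase; refinement
  acceptance is non-strict (lexicographic on density, then total
  similarity, with a `1e-9` tolerance for float comparisons).
* The weakest-row choice in refinement breaks ties by lowest row index;
  `which.max`-style first-index tie-breaks are used throughout, so runs
  are reproducible bit for bit.
* Weights in `(1, 1000]` are interpreted as STRING-style combined scores
  and divided by 1000 at load time; self-loops are dropped; duplicate
  edges keep the maximum weight.
* Degenerate inputs: alignments below two rows have density and ISC 0 by
  convention; an alignment whose columns exhaust a network's nodes (or
  their neighbourhoods) simply stops extending; `refine = 0` is a no-op.

## The synthetic benchmark

`fixtureSpec()` / `generateFixture()` build the study conditions used
throughout the test suite: by default three networks of 60 proteins,
Erdős–Rényi background at edge probability 0.05 with weights uniform in
`[0.1, 0.5]`, and two planted complexes of six counterpart proteins per
network wired with probability 0.9 at weights in `[0.7, 1.0]`.
Counterpart pairs receive bit score 200; random decoy pairs (60 per
network pair) score below 20.  The weight bands separate background from
planting both for the density objective and for the colour classes; the
similarity gap makes correct counterpart matching identifiable.  Nodes
are named `C<complex>_N<network>_P<member>` so the ground truth is
self-describing, and `scoreRecovery()` computes exact-row recall and
precision against it.

What the generator does **not** emulate: scale-free degree
distributions, correlated noise between interaction weight and homology,
missing orthologs (every planted row is complete in every network), and
paralog ambiguity.  Passing the planted-recovery tests therefore
demonstrates that the search machinery works under detectable plantings,
not that any particular biological dataset will yield complexes of a
given quality.

Problem sizes in the tests and the acceptance script — 20 studies of
3 × 60-node networks, 100 seed-optimality instances with five candidates
per network, 200-case oracle sweeps for ISC and overlap filtering — were
chosen as the smallest sizes at which the stochastic assertions are
stable across seeds.

## Known limitations

* The search is sequential by design (determinism contract); restarts are
  not parallelised.
* Directed networks and multi-edges are out of scope; edge weights must
  be probabilities after rescaling.
* A decoy-seeded alignment can occasionally absorb part of a true complex
  in an inconsistent column order and, being larger, outlive the clean
  recovery in the overlap filter; refinement swaps one row at a time and
  cannot untangle multi-row misassembly.  This is visible in the
  planted-recovery studies as occasional sub-perfect recall and is the
  cost of the greedy acceptance rules.
* GO annotations are decorative by construction: they are attached to
  alignment-graph nodes after the fact and are never read by the search
  (asserted by a byte-identity test).

## A worked run

```{r demo, eval = FALSE}
fx <- generateFixture(fixtureSpec(seed = 1))
cfg <- alignmentConfig(sigma = 2, seed = 1)   # sparse networks: sigma 2
res <- alignNetworks(fx$networks, fx$similarity, cfg)
res[[1]]
scoreRecovery(res, fx$truth)
```

The command-line equivalent is `ppialign demo --seed 1` (installed under
`exec/`), which also writes the fixture files, one result file per
alignment, and prints recall and precision.
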