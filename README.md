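# ppiAlign

Multiple local alignment of protein–protein interaction (PPI) networks:
detection of conserved protein complexes across two or more species by a
greedy, stochastic, Gibbs-sampling search.

## What it does and for whom

Comparing the PPI networks of evolutionarily distant species can reveal
functional modules — ribosomes, spliceosomes, kinase and repair
complexes — that are conserved as *wired units* even when sequence
comparison alone is inconclusive. `ppiAlign` is for systems biologists
who have two or more weighted interaction networks (e.g. STRING exports)
plus cross-species protein similarity (BLAST bit scores, or COG/KOG/NOG
orthology-group membership) and want a ranked list of candidate
conserved complexes with an explicit one-to-one protein mapping.

## The method

An *alignment* of networks G₁ … G_N is an ordered set of rows, each row
a tuple (p₁, …, p_N) with pᵢ ∈ Gᵢ, injective within every network
column. The search has three phases:

1. **Bootstrap.** A seed row is drawn from the candidates of degree ≥ σ
   by Gibbs sampling: network k's member is resampled with probability
   ∝ ε + Σ_{j≠k} s(p, p_j), where s is the cross-network similarity
   (bit score, or shared-group count). The best row visited is kept and
   polished by coordinate ascent.
2. **Extension.** Each step samples one additional row from the unused
   neighbours of the aligned subgraphs, with member weights
   ε + similarity + summed edge weight into the member's column. A step
   is kept only while it strictly increases the growth density
   d(A) = mean_i ( Σ w(e), e induced in Gᵢ ) / k  (k rows); otherwise
   the phase stops.
3. **Refinement.** For a fixed number of iterations the
   lowest-contribution row is swapped for a freshly sampled one whenever
   the objective (d(A), ties by total row similarity) does not decrease.

Results below the minimum complex size are dropped, heavily overlapping
alignments are deduplicated (the smaller of a conflicting pair dies),
and the survivors are ranked by size and by the **Index of Structural
Conservation**,

ISC = 100 · mean over network pairs (i, j) of 2 |C_ij| / (|E_i| + |E_j|),

where E_i, E_j are the induced edge sets and C_ij the edges conserved
under the row correspondence. Reported *density* is the normalized mean
induced edge weight Σ w(e) / C(k, 2) ∈ [0, 1].

The six user-facing parameters and their defaults: `iterSeed = 200`,
`iterExtend = 200`, `sigma = 7` (1–2 recommended for sparse networks),
`overlap = 0.5`, `refine = 10`, `minComplexSize = 5`. Runs are
deterministic given the RNG seed.

## Worked example

The package ships a synthetic-benchmark generator whose defaults plant
two 6-protein complexes in three sparse 60-protein networks:

```r
library(ppiAlign)
fx  <- generateFixture(fixtureSpec(seed = 1))
cfg <- alignmentConfig(sigma = 2, seed = 1)   # sparse networks: sigma = 2
res <- alignNetworks(fx$networks, fx$similarity, cfg)
res[[1]]
#> Alignment of 3 networks (net1, net2, net3): 6 rows
#>   density 0.7745  ISC 90.21%
#>   C2_N1_P6 <-> C2_N2_P6 <-> C2_N3_P6
#>   C2_N1_P5 <-> C2_N2_P5 <-> C2_N3_P5
#>   C2_N1_P2 <-> C2_N2_P2 <-> C2_N3_P2
#>   ...
scoreRecovery(res, fx$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

Both planted complexes are recovered exactly: every reported row maps
each planted protein to its counterpart in the other two networks
(recall and precision 1), the aligned subgraphs carry high weights
(density 0.77) and agree on 90% of their wiring (ISC 90.21%).

The same pipeline is scriptable from a shell via the installed
`exec/ppialign` entry point:

```sh
ppialign align --net worm.txt --net fly.txt --net yeast.txt \
         --sim bitscores.tsv --sim-format bitscore --out results/ \
         --sigma 2 --seed 7
ppialign demo --seed 1          # self-contained synthetic run
ppialign demo --list-params     # print the six defaults
```

`align` writes one text file per alignment (subgraphs + one-to-one
mapping), one GraphML alignment graph per alignment (solid
weight-coloured intra-edges, dashed inter-edges), and a manifest with
the exact configuration and input checksums.

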