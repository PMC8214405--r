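---
title: "Measuring protein interactome resilience under experimental evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein interactome resilience under experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiresilience)
```

## The question and the model

A bacterial protein interactome is an undirected graph: proteins as nodes,
physical interactions as edges. Loss-of-function mutations — nonsense
SNPs, small indels, mobile-element insertions, large deletions hitting a
coding region — are treated as removing the affected protein and all its
interactions. As such disruptions accumulate over tens of thousands of
generations of experimental evolution, does the network fragment as fast
as random gene loss would predict, or does selection steer mutations away
from the proteins that hold the network together?

The package operationalizes this with three ingredients.

**Resilience.** For a network $G$ with $N$ nodes and failure rate
$f_k = k/K$, $k = 0,\dots,K-1$, remove $\lfloor f_k N\rfloor$ nodes
uniformly at random and take the normalized Shannon entropy of the
component-size distribution of the remainder,
$H = \left[-\sum_i \frac{c_i}{N'}\ln\frac{c_i}{N'}\right] / \ln N'$,
singletons included. Resilience is $R(G) = 1 - \frac1K\sum_k
\mathbb E[H(G,f_k)]$. A clique scores exactly 1 (one component at every
rate), an edgeless graph exactly 0 (all singletons at every rate), and
real interactomes sit in between; what carries information is not the
absolute value but how it changes along an evolutionary trajectory.

**Pruned evolved networks.** Each sampled clone's network is the ancestral
interactome minus its disrupted genes. Neighbours of removed proteins that
lose their last interaction stay in the graph as singletons — they are
still proteins, just isolated — which matters because the entropy counts
singleton components. Disrupted genes without interactions are tolerated
(disruption tables routinely cover the whole genome, the interactome only
part of it) and counted in logs.

**Randomized counterparts.** For every clone, replicate disruption sets of
exactly the clone's size $n$ are drawn and scored on the same failure
grid. Scheme A samples uniformly from all protein-coding genes, essential
genes included; scheme B restricts to genes disrupted in at least one
population and weights each by the number of populations disrupting it
(sequential sampling without replacement, probabilities proportional to
the weights among genes still available). Replicates are independent
across timepoints — deliberately no phylogenetic nesting, trading realism
for cheap, statistically independent replicates.

The headline comparison treats populations as the unit of replication:
per population, fit an OLS slope of resilience over generation using all
clone points for the evolved series, and for the null the mean of
per-replicate slopes; then run an exact Wilcoxon signed-rank test on the
12 paired differences, one-sided by default with the alternative "evolved
slopes are larger" (resilience lost more slowly). With 12 populations the
smallest attainable one-sided p is $2^{-12} \approx 0.00024$; observing it
means every population beat its null.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 100 (10 in tests) | failure-grid steps; $f = 1$ excluded (total removal carries no information and makes the normalizer degenerate) |
| `M` | 50 (10 in tests) | Monte-Carlo removal replicates per network |
| `R` | 100 (8–20 in tests) | randomized replicate sets per clone per scheme |
| `seed` | — | one global seed; every clone/replicate derives its own stream |

The comparisons are between slopes of the same statistic under the same
grid, so conclusions depend on *relative*, not absolute, resilience; `K`
and `M` trade precision for time and are recorded in every output and in
the run manifest. Because the entropy normalizer is $\ln N'$ of the
*post-removal* node count (defined as 0 when $N' \le 1$), the statistic is
comparable across networks of different sizes.

Determinism: per-network seeds derive from (global seed, clone identity)
and per-replicate seeds from (seed, population, generation, clone, scheme,
replicate), via a string hash modulo $2^{31}-1$. Results are therefore
bit-reproducible and independent of evaluation order, and safe to
parallelize.

## Numerical choices

- The Monte-Carlo curve uses checkpoints along M random removal
  permutations rather than an independent subset per rate — the two are
  distributionally identical, and reverse node addition with a union-find
  makes each replicate $O(N + E)$. The component-size entropy is updated
  incrementally from $\sum_i c_i \ln c_i$.
- $\lfloor f_k N\rfloor$ is computed as integer $\lfloor kN/K\rfloor$, so
  the grid cannot drift off by one through floating-point.
- The exact signed-rank test drops zero differences, assigns average ranks
  to ties, and computes the full $2^n$ sign-assignment distribution by a
  generating-function recursion on doubled ranks (half-integer tie ranks
  become integers). Two-sided p is the probability of a deviation from the
  null mean at least as large as observed.
- The rank-sum test is exact for samples up to 10+10 *including ties*
  (dynamic programming over assignments of the tie-averaged pooled ranks);
  larger samples use the normal approximation with tie and continuity
  corrections, and the output records which branch ran.
- Binomial tails accumulate log-probabilities (no underflow at
  p ≈ 10⁻¹⁶); Fisher's exact test sums hypergeometric tails, with the
  usual "no more probable than observed" rule two-sided.
- The single-gene scan scores the background and every single-removal
  network under one common derived seed (common random numbers), so the
  deltas $R(G-g) - R(G)$ are differences of positively correlated
  estimates and most Monte-Carlo noise cancels.
- Genomic distance between interacting genes is the shorter arc between
  gene midpoints on the circular chromosome — symmetric, strand-free, and
  bounded by $L/2$; wrap-around genes get wrap-aware lengths and
  midpoints.

## The synthetic world

`simulation_config()` states a reduced-scale analog of the real
experiment: a duplication–divergence interactome (duplicate a random
protein, retain each parental interaction with probability 0.4, attach to
the parent with probability 0.7), which yields the heavy-tailed degree
distributions of real interactomes; a gene universe ~2× the interactome,
placed in random order on a circular chromosome so genomic position is
independent of network topology; essential flags at the empirical
bacterial fraction 541/4112, biased toward high-degree proteins
(odds factor 1.3 per unit degree, capped) to emulate the observed PPI
enrichment of essential genes; 12 populations × 11 timepoints × 2 clones,
six populations with 4× mutator rates and one with a 3× transposon-burst
mobile-element insertion rate; and saturating fitness
$w(t) = (1 + ct)^b$ with log-normal noise.

Disruption rates (1.5 events per 5,000 generations per non-mutator
lineage) are order-of-magnitude placeholders scaled to the reduced gene
universe — no published per-population rates exist to copy — and are
flagged as such. Selection enters only as (i) candidate genes drawn with
probability $\propto (\text{degree}+1)^{-\gamma}$ and (ii) essential-gene
candidates rejected with probability `essential_protection`. This encodes
*purifying* selection on hubs and essential genes, not direct optimization
of resilience, matching the interpretation that resilience maintenance is
a byproduct. Multi-gene deletions are contiguous blocks in genomic order;
clones at a timepoint share their lineage's disruptions plus private ones,
giving the nested, phylogenetically correlated structure the evolved (but
not the randomized) series should have.

What a green test does establish: the estimator pipeline is unbiased and
calibrated under its null, recovers planted selection, and respects every
size/eligibility contract. What it does not establish: realism of the
mutation spectrum, within-population polymorphism (one lineage per
population), gain of interactions, or evolution of essentiality — all
deliberately out of scope.

## Calibration design, and a caveat about deletion blocks

The type-I-error criterion simulates the neutral world (γ = 0, protection
= 0) 300 times at reduced scale and checks that the paired test rejects at
α = 0.05 within binomial sampling error. The calibration world uses
`deletion_block_rate = 0`: the signed-rank null model assumes the 12
population differences are independent, and exchangeable single-gene
disruptions satisfy that. Contiguous deletion blocks do not — all 12
populations share one genome placement, so block draws acquire a common
placement-dependent deviation that *correlates* populations and
overdisperses the test statistic. By symmetry the deviation is mean-zero
over placements — a contiguous window of a uniformly permuted gene order
is marginally a uniform gene set — so the effect is on the variance of the
test statistic, not a bias of the slopes. This mirrors a limitation the original analysis acknowledges for
its own resampling design — randomization replaces deletion blocks by
independent single-gene draws — and is why the package carries the two
block diagnostics (PPI degree by mutation class, and genomic distances of
removed interactions) rather than a claim that the paired test is exactly
calibrated in the presence of large deletions.

Zero-disruption clones (early timepoints) cannot appear in a record-style
disruption table, so the pipeline accepts a clone roster
(`clone_roster()`); clones on the roster without records are scored as the
intact ancestor and anchor each population's slope at generation 0, for
the evolved and null series symmetrically.

## Open choices made here

- The slope estimator is plain OLS over all clone points, and the null
  summary is the mean of per-replicate slopes (the alternative — slope of
  replicate means — is available behind a flag); both conventions are
  recorded in the manifest.
- The headline test is one-sided by default: the exact minimum
  $p = 2^{-12}$ at $n = 12$ is only attainable one-sided, which fixes the
  convention.
- A clone's randomized-set size counts all its distinct disrupted genes,
  whether or not they are in the interactome (`count = "all"`), since the
  design fixes the number of *proteins disrupted*, not the number of
  network nodes removed; `count = "in_network"` is available.
- An interaction removed by both a deletion-block gene and a separately
  disrupted gene counts as deletion-removed (deletion precedence;
  configurable).
- "Essential and nearly essential" genes are one essential class.
- Config files are JSON (no YAML parser in the supported stack); the
  content is the same single declarative document with one seed.

## Known limitations

Targeted (degree-ordered) attack curves, percolation-threshold estimation,
degree-preserving rewiring nulls, phylogenetically nested null histories,
and GenomeDiff parsing are non-goals. The Monte-Carlo scorer is exact only
in expectation; for production comparisons keep `M ≥ 50`, and for
single-gene scans rely on the common-random-numbers deltas rather than
absolute values. The exact signed-rank implementation supports up to 25
nonzero differences (the enumeration regime); beyond that a large-sample
test should be used instead.
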