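# ppiresilience

Tools for asking whether the resilience of a protein–protein interaction
(PPI) network is maintained by selection during long-term experimental
evolution, in the style of analyses of Lenski's long-term evolution
experiment (LTEE) with *E. coli*: 12 initially identical populations,
clones sampled at 11 timepoints through 50,000 generations, each clone
carrying an accumulating set of loss-of-function "gene disruptions"
(nonsense SNPs, small indels, mobile-element insertions, large deletions).

The package is aimed at evolutionary systems biologists who have (a) an
ancestral interactome as an edge list, (b) a gene table with circular
chromosome coordinates and essentiality flags, and (c) a per-clone
disruption table — or who want to simulate all three.

## The statistic

An evolved clone's network is the ancestral interactome pruned of its
disrupted proteins. Network resilience is measured by random node failure:
for failure rates `f_k = k/K` (k = 0, …, K−1), remove `⌊f_k·N⌋` nodes
uniformly at random and record the normalized Shannon entropy of the
connected-component size distribution,

    H(G, f) = [ −Σ_i (c_i/N') ln(c_i/N') ] / ln(N'),

with `c_i` the component sizes (singletons included) and `N'` the
post-removal node count. Resilience is

    R(G) = 1 − (1/K) Σ_k E[H(G, f_k)],

estimated by Monte-Carlo (M removal replicates per network; a union-find
percolation kernel in C++ makes this cheap). `R = 1` means the network
stays connected under any partial failure; `R = 0` means it is already
dust.

Each population's rate of resilience change (OLS slope over all clone
points) is compared against matched randomized networks under two schemes:

* **scheme A** (`uniform_all`) — disrupted proteins resampled uniformly
  from *all* protein-coding genes, essential genes included;
* **scheme B** (`weighted_disrupted`) — resampling restricted to genes
  disrupted in ≥1 population, weighted by the number of populations that
  disrupted them (parallelism-aware).

The per-population differences (evolved slope − mean null slope) go into
an exact Wilcoxon signed-rank test; with 12 populations all favouring the
evolved networks the one-sided exact p-value is 1/4096 ≈ 0.00024.

## Worked example

Everything below is synthetic — the generator emulates the experiment's
design (12 populations, 11 timepoints, 2 clones per timepoint, mutator and
transposon-burst populations, a purifying-selection knob) at reduced scale:

```r
library(ppiresilience)

cfg <- simulation_config(seed = 42)     # 200-protein interactome, 400 genes
exp <- generate_experiment(cfg)
#> <simulated_experiment: 200-node interactome, 400 genes, 12 populations,
#>  6168 disruption records>

grid <- failure_grid(K = 10, M = 10, seed = 42)
res <- run_full_analysis(exp$network, exp$genes, exp$disruptions,
                         fitness = exp$fitness, grid = grid, R = 20,
                         clones = clone_roster(exp), quiet = TRUE)

head(res$evolved, 3)
#>   population generation          clone n_disrupted resilience
#> 1      Ara+1          0    Ara+1_t0_c1           0  0.6070058
#> 2      Ara+1          0    Ara+1_t0_c2           0  0.6020510
#> 3      Ara+1       5000 Ara+1_t5000_c1           3  0.5955621

res$tests$paired_resilience_uniform_all
#> <paired_resilience_uniform_all (exact): statistic=78, p=0.0002441,
#>  alternative=greater, n=12>
res$tests$paired_resilience_weighted_disrupted
#> <paired_resilience_weighted_disrupted (exact): statistic=58, p=0.07568,
#>  alternative=greater, n=12>
res$tests$fitness_resilience_correlation
#> <pearson_correlation: statistic=-0.165477, p=0.05793,
#>  alternative=two_sided, n=132>
```

Read: all 12 evolved populations lose resilience more slowly than their
uniformly randomized counterparts (the exact one-sided minimum,
p = 0.00024); the disruption-frequency-weighted null is, as expected, much
harder to beat; and resilience declines while fitness rises (negative
correlation), the signature of purifying rather than positive selection on
resilience. `res$slopes` holds the per-population rates per series,
`res$tests` the full battery (degree-by-mutation-class, removed-interaction
genomic distances, essential-gene PPI enrichment, essential disruption
deficit), and with `outdir=` every table lands as TSV next to a JSON run
manifest recording the grid, seeds and conventions.

The same analysis runs from TSV files via the CLI:

```sh
./exec/ppiresilience simulate --config cfg.json --out sim/
./exec/ppiresilience analyze --edges sim/edges.tsv --genes sim/genes.tsv \
    --disruptions sim/disruptions.tsv --fitness sim/fitness.tsv \
    --out run/ --K 100 --M 50 --R 100 --seed 1
./exec/ppiresilience report --out run/
```

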