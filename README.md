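# leprimalign

Pairwise **local alignment of protein–protein interaction (PPI) networks**
to predict evolutionarily conserved modules — pairs of clusters, one per
species, whose internal interactions and orthologous membership are
mutually conserved. The package implements the LePrimAlign algorithm
(Local Entropy-based PageRank-inspired Markovian Alignment) together with
the field's standard evaluation metrics and a deterministic synthetic
benchmark generator.

## Who this is for

Computational biologists comparing interactomes across species: given two
weighted PPI networks (edge weights = interaction confidence, e.g. simGIC
semantic similarity) and cross-species sequence-similarity scores (e.g.
−log BLAST e-values), the package returns pairs of aligned clusters that
are candidate conserved protein complexes.

## The method

1. **Global alignment (PrimAlign preprocessing).** The two networks plus
   their crosslinks form one Markov chain with block transition matrix

   ```
   T = [ T11 T12 ]      within-network blocks: edge weights
       [ T21 T22 ]      cross blocks: weighted sequence similarity
   ```

   rows normalized to sum to 1. A damped power iteration with teleport
   correction for dangling rows yields the stationary distribution *p*,
   and each crosslinked pair (v1, v2) gets

   `S_global(v1,v2) = (p(v1)·T12[v1,v2]/‖T12[v1,·]‖ + p(v2)·T21[v2,v1]/‖T21[v2,·]‖)·n`

   followed by log normalization `S_norm = log_b(1 + S_global)` with
   `b = ⌈1 + max S_global⌉`, so all normalized scores lie in [0, 1].

2. **Seed selection and graph-entropy clustering.** Pairs with
   `S_global > θ` are processed in descending score order. Around each
   seed node an initial cluster is formed: seed plus neighbours, then
   neighbours are greedily removed (heaviest weighted degree first) when
   removal strictly lowers the graph entropy
   `e(G) = Σ_v −p_i(v)log₂p_i(v) − p_o(v)log₂p_o(v)`, where `p_i(v)` is
   the share of v's weighted degree pointing into the cluster.

3. **Match/gap scoring and expansion.** For clusters C1, C2 an edge of C1
   is a *match* if its endpoints' alignment partners are adjacent in C2,
   and a *gap* if they are joined through one unaligned intermediate
   node. The directional score is

   `S_local(C1,C2) = γ·S_inter + (1−γ)·S_intra`,
   `S_intra = (Σ_match w + β·Σ_gap w)/|E1|`,
   `S_inter = mean_v max_u S_norm(v,u)`.

   Boundary nodes are added greedily (highest degree first) while they
   strictly increase the cluster's own directional score. Pairs where
   both clusters have ≥ 2 members and both directional scores are at
   least 0.02 are emitted; their nodes are marked visited.

Defaults: `θ = 1`, `β = 1`, `γ = 0.25`, damping `α = 0.85`.

## Worked example

```r
library(leprimalign)

inst <- generate_pair(synthetic_spec(seed = 42L))   # planted benchmark
fit  <- leprimalign(inst$g1, inst$g2, inst$xl)
print(fit)
#> Local PPI network alignment (LePrimAlign)
#>   networks: 38 and 38 nodes; 46 crosslinked pair(s) scored
#>   theta = 1, beta = 1, gamma = 0.25
#>   conserved module pairs emitted: 6
summary(fit)
#> 6 aligned cluster pair(s)  [theta=1 beta=1 gamma=0.25]
#>  pair    seed1    seed2 size1 size2 s_local_12 s_local_21
#>     1 s1_m3_04 s2_m3_04     5     5  0.7521301  0.7521301
#>     2 s1_m2_01 s2_m2_01     6     6  0.4626776  0.7575038
#>     3 s1_m1_04 s2_m1_04     6     2  0.2754727  0.9387136
#>     4 s1_m1_05 s2_m1_05     5     5  0.6626109  0.8223179
#>     5 s1_m3_02 s2_m3_02     6     5  0.6879894  0.7371908
#>     6 s1_m2_05 s2_m2_05     6     2  0.1153488  0.9162694
recovery_fscore(fit, inst$truth)
#> [1] 0.8093434
```

The instance plants three 6-node dense modules in each of two 38-node
networks (the second carries relabeled copies with 10% edge dropout).
Six cluster pairs are emitted; the larger, symmetric ones recover the
planted modules (mean best-match f-score 0.81 against ground truth), the
small asymmetric ones are noise-driven fragments whose directional scores
still clear the 0.02 floor.

File-based workflow:

```sh
Rscript inst/cli/leprimalign.R simulate --out-prefix sim --seed 5
Rscript inst/cli/leprimalign.R align --net1 sim.net1.tsv --net2 sim.net2.tsv \
    --xlinks sim.xlinks.tsv --out-prefix run
Rscript inst/cli/leprimalign.R eval  --net1 sim.net1.tsv --net2 sim.net2.tsv \
    --xlinks sim.xlinks.tsv --clusters1 run.clusters1.tsv \
    --clusters2 run.clusters2.tsv --out report.tsv
```

`align` writes two row-aligned cluster files (row *i* of each file is one
aligned pair). `eval` reports per-pair sizes, optional best-match
f-scores and inter-species semantic similarity, and conserved-edge
counts.

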