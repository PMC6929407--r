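---
title: "Predicting conserved modules by local PPI network alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting conserved modules by local PPI network alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leprimalign)
```

## The problem

Protein interactions that persist across species are strong evidence of
functional conservation. Local network alignment looks for *pairs* of
clusters — one subgraph per species' PPI network — whose internal edges
and orthologous membership mirror each other. This package implements
the LePrimAlign approach: a global, many-to-many Markov-chain node
correspondence is computed first and then refined locally around
high-scoring seed pairs into conserved module candidates.

Inputs are two weighted undirected PPI networks (weights in [0, 1],
interpreted as interaction confidence such as simGIC semantic
similarity of the interacting partners) and a table of non-negative
cross-species sequence-similarity scores (typically −log BLAST
e-values). Nothing in the package computes these scores; they are
experimental inputs.

## The model, stage by stage

### Markov-chain global alignment

Both networks are stacked into one state space of size
$n = n_{G_1} + n_{G_2}$. The transition matrix has four blocks: within
each network a random walker moves along interactions proportionally to
their weight; between networks it jumps along crosslinks proportionally
to `cross_weight` times the sequence-similarity score. Rows are
normalized to sum to one; nodes with no outgoing mass at all (isolated,
uncrosslinked) are *dangling* and handled by the teleport correction of
the damped power iteration

$$p^{(t+1)} \propto \alpha\, p^{(t)} T + \bigl(\alpha\, p^{(t)} q + 1 -
\alpha\bigr)\tfrac{u}{n},$$

renormalized to unit L1 norm each step. The pair score multiplies each
endpoint's stationary probability by the share of its cross-network
transition mass directed at the partner, sums the two directions, and
scales by $n$. Because a handful of pairs score far above the bulk, the
scores are log-normalized, $S_{norm} = \log_b(1 + S_{global})$ with
$b = \lceil 1 + \max S_{global}\rceil$, mapping them into [0, 1] with
the maximum exactly at 1 whenever $1 + \max$ is integral.

Parameter choices made here, where the procedure leaves them open: the
damping factor defaults to $\alpha = 0.85$ (the customary PageRank
value), `cross_weight` defaults to 1 (sequence scores enter at face
value), iteration starts from the uniform distribution, and convergence
is declared when the L1 change drops below $10^{-10}$ (cap 1000
iterations, with a warning on hitting the cap). All are arguments. The
normalization base is floored at 2 so the logarithm stays valid on
degenerate inputs whose maximal score is below 1.

### Graph-entropy seed clustering

Crosslinked pairs with $S_{global} > \theta$ become seeds, processed in
descending score order (ties broken lexicographically for determinism).
For a cluster $C$, a node's inner-link probability $p_i(v)$ is the
fraction of its weighted degree pointing into $C$, and its entropy is
the binary entropy of $p_i(v)$; the graph entropy is the sum over all
nodes. Around each seed the cluster starts as seed-plus-neighbours and
each neighbour, visited once in decreasing weighted-degree order, is
removed iff that strictly lowers the graph entropy. Two conventions the
formulas do not fix: isolated nodes get $p_i = 0$ and entropy 0, and
weighted-degree ties are broken lexicographically. Removal trials are
evaluated incrementally — only the removed node's neighbours change
entropy — which is provably identical to recomputing the full sum (a
property the test suite checks on random triples).

### Match/gap scoring and greedy expansion

"Aligned", for scoring purposes, means the node pair carries any
positive global score — the whole crosslink universe, no threshold. An
edge of $C_1$ is a **match** when some pair of partners of its
endpoints is adjacent within $C_2$, and a **gap** when (not being a
match) such partners are joined by a 2-edge path through an
intermediate node of $C_2$ that is aligned to no node of $C_1$. Longer
detours count as neither; an edge qualifying as both counts as a match.
The directional score mixes conservation and correspondence:

$$S_{local}(C_1, C_2) = \gamma\, S_{inter} + (1 - \gamma)\, S_{intra},$$

with $S_{intra}$ the matched (and $\beta$-discounted gapped) weight
fraction of $C_1$'s edges and $S_{inter}$ the mean best normalized
score from $C_1$'s nodes into $C_2$. Defaults $\beta = 1$,
$\gamma = 0.25$, $\theta = 1$ follow the method's standard setup
(accuracy is insensitive to $\beta$; lower $\theta$, e.g. 0.1, suits
network pairs with few known orthologs and hence few candidate seeds).

Expansion alternates passes over the two clusters: each pass enumerates
the cluster's outer boundary in descending (unweighted) degree order
and keeps a node iff it strictly increases that cluster's own
directional score, stopping when a full pass accepts nothing. A pair is
emitted when both clusters have at least two members and both
directional scores reach 0.02; emitted nodes are marked visited, and
later seed pairs are skipped only when *both* endpoints are visited.

Two design points deserve note. First, scores during expansion are
recomputed from scratch at every trial rather than updated
incrementally: emitted clusters are small (tens of nodes), the
from-scratch evaluation is exact by construction, and it keeps the
scoring path identical to the documented formulas. Second, the greedy
acceptance rule cannot absorb a *mutually* missing counterpart pair —
if neither cluster contains the other's counterpart, adding either node
alone dilutes both score components (its edges are unconserved until
the partner joins, and it has no partner to raise $S_{inter}$), so both
additions are rejected; the test suite pins this behaviour down. This
is inherent to one-node-at-a-time greedy expansion under a strict
improvement rule, not an implementation choice.

## Evaluation metrics

`fscore()`/`mean_best_fscore()` compare predicted clusters with a
complex catalog via the harmonic mean of recall and precision, taking
each cluster's best match. `iss()` averages pairwise inter-species
semantic similarity over the cross product of an aligned pair.
`conserved_edges()` counts, per edge of one cluster, the distinct edges
of the partner cluster whose endpoints are crosslinked with its own
(one edge conserved by several partner edges counts once per partner
edge); the functionally consistent variant additionally requires both
endpoint similarities to exceed 0.2 strictly. Both directions are
reported, since the count is defined from one side's edge set.
`filter_overlapping()` removes highly overlapping clusters (Jaccard
index above 0.4), keeping the largest — the standard pre-filter before
comparing cluster counts across methods.

## The synthetic benchmark

`synthetic_spec()`/`generate_pair()` build paired instances with known
ground truth: dense planted modules (default three modules of six
nodes, within-module edge probability 0.9, weights uniform on
[0.6, 1]), relabeled copies in the second network with 10% edge
dropout, independent background in each network (20 extra nodes, edge
probability 0.05, weights uniform on [0.05, 0.4]), bijective
counterpart crosslinks at score 100 on the −log e-value scale, and 2%
spurious crosslinks at score 5. A module realization whose density
fails to exceed the background rate is redrawn. One integer seed drives
everything through a private RNG stream, so instances are reproducible
and the caller's RNG state is untouched.

The background node count (20 against 18 planted nodes) and the two
crosslink score levels are this package's own calibration of a
realistic noise floor: roughly half of each network is unannotated
noise, and ortholog scores dominate spurious hits by an order of
magnitude, as they do after any sensible BLAST cutoff.

What the generator does *not* emulate: scale-free degree structure,
hub proteins shared between modules, many-to-many orthology within
modules, or correlated noise between the two networks. Passing the
recovery benchmarks therefore demonstrates algorithmic correctness on
density-contrasted instances, not expected accuracy on genome-scale
interactomes.

## Problem sizes and numerical checks

The shipped tests and the acceptance script run at deliberately small
scale — networks up to ~50 nodes for oracle comparisons and 38-node
paired instances (20 seeds) for recovery — where every quantity can be
cross-checked against dense brute-force reimplementations: the sparse
stationary distribution against a dense power method (L1 agreement
within $10^{-8}$), incremental entropy against the full sum (within
$10^{-9}$), and the scoring algebra against hand-computed instances.
Determinism is enforced end to end: all orderings are explicitly
tie-broken, so identical inputs give byte-identical output files.

## Known limitations

* Runtime grows with the number of seeds times cluster neighbourhood
  size; the single-threaded from-scratch rescoring is comfortable at
  benchmark scale but would need incremental bookkeeping for
  genome-scale interactomes with tens of thousands of seeds.
* The two-file edge-list format cannot represent isolated nodes, so
  they are dropped on a write/read round trip (they cannot join any
  cluster of size ≥ 2 anyway).
* Cluster pairs are emitted greedily per seed; overlapping or fragment
  pairs can appear under noise (the Jaccard filter is available for
  post-processing).
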