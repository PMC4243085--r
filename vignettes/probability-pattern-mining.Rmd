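---
title: "Circuit-based probability isomorphism and frequent pattern mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit-based probability isomorphism and frequent pattern mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upm)
```

## The model

An uncertain biological network is a simple graph whose edges carry
existence probabilities in (0, 1]: confidence-scored protein interactions,
probabilistic regulatory links. Two k-node probability graphs are
*probability isomorphic* when some node bijection keeps every corresponding
per-edge probability difference within `alpha` and the summed absolute
difference within `theta`; absent edges count as probability 0, so the
criterion covers topology and weights at once. A *frequent probability
pattern* at scale k is a class of mutually probability-isomorphic k-node
subgraphs of the host network whose size (support) reaches `min_sup`.

Deciding probability isomorphism by definition means searching k!
bijections per pair, for every pair of candidates. The package's core idea
replaces most of that work with a circuit invariant.

### The associated circuit and its voltage signature

Each edge of probability p becomes a resistor of conductance p. Fixing a
reference node i and injecting a unit current into every other node
(complete excitation), Kirchhoff's laws give the node-voltage system
`G U = 1`, where `G` is the weighted Laplacian of the graph with row and
column i deleted. For a connected graph with positive edge probabilities,
`G` is an irreducibly diagonally dominant M-matrix: nonsingular with a
nonnegative inverse, so every voltage is strictly positive — degeneracy can
only come from disconnection, which is rejected up front with an explicit
error.

Sorting the k−1 voltages ascending gives the sequence `S_i`; stacking all k
sequences gives the voltage matrix `S`. Relabelling the graph permutes the
rows of `S` but changes no row, so the multiset of rows is a graph
invariant. It is a *necessary-condition* invariant: probability-isomorphic
graphs have similar voltage matrices, but agreement of voltages does not
prove isomorphism (the classical limitation of spectral-style signatures).
Linearity of the system also gives a useful self-check: scaling every
probability by c scales every voltage by exactly 1/c, which the test suite
asserts to 1e−12.

### The staged decision

For a pair of k-node graphs the test proceeds:

1. Build both voltage matrices and the matrix of squared Euclidean
   distances between their rows; solve the linear sum assignment problem on
   it (Hungarian algorithm, via `clue::solve_LSAP`). The optimal cost is
   `VMval`. If `VMval > epsilon`, reject — stage `voltage-filter-reject`.
2. The assignment is also a node mapping. Compute
   `PMval = sum_{i,j} |p(i,j) − p'(i,j)|` over ordered index pairs under
   that mapping; if `PMval <= theta`, accept — stage `hungarian-accept`.
3. The Hungarian mapping is optimal for voltages, not adjacencies, so a
   failure at step 2 is not conclusive. Remaining bijections are searched
   in lexicographic order with branch-and-bound (a partial mismatch
   already above `theta` prunes the branch), accepting on the first mapping
   within `theta` — stages `permutation-accept` / `permutation-reject`.

Exact graph isomorphism is the `epsilon = theta = 0` special case (up to
floating point; the suite checks `VMval <= 1e-9` on relabelled copies).

## Tunable parameters

* `epsilon` (voltage mismatch, squared-volt units) and `theta` (summed
  probability mismatch, dimensionless): default `ln(k(k−1))` for scale-k
  subgraphs, the upper-limit heuristic under which cluster counts remain
  compact while jittered copies of a pattern still merge. Cluster count is
  monotone non-increasing in both (asserted on the planted-pattern suite).
* `alpha` (per-edge threshold, off by default): the definitional per-edge
  condition is expensive and largely subsumed by the voltage filter, so by
  default only the summed criterion is enforced; a strict mode re-enables
  the per-edge check inside stages 2–3.
* `augment` (default on): each voltage row is extended with its mean and
  variance before the distance computation, tightening the voltage filter.
* `min_sup`: post-hoc support filter; clustering itself never uses it, so
  lowering `min_sup` never changes the clusters, only which are reported.
* `max_permutation_k` (default 8): refusal cap for the factorial stage.

### Interpretation choices

Several quantities admit more than one reading; the package fixes them as
follows and documents rather than hides the choice:

* **Excitation sign.** "Current from the reference node to the others" could
  put +1 or −1 on the right-hand side; the +1 convention is the one that
  reproduces the positive benchmark voltages of `example4_graph()`.
* **Distance is squared.** The row distance is the Gram expansion
  `‖a‖² + ‖b‖² − 2a·b` with no square root; only relative order and the
  user-set `epsilon` depend on the scale.
* **PMval counts ordered pairs.** For undirected graphs every edge
  difference therefore appears twice. The default `theta` is calibrated on
  this doubled scale, and `adjacency_mismatch()` documents it.
* **Augmentation variance** is the population variance of the k−1 voltages
  (divide by k−1, the sequence length), appended to each row (together with
  the mean) so that it enters the same Euclidean distance.
* **Cluster "union".** Merging clusters must produce a new representative;
  the package uses the support-weighted mean of the aligned probability
  adjacencies, which keeps the representative a valid probability graph and
  makes support a true weight. A strict `merge_rule = "first"` keeps the
  first member instead.
* **Phase-2 cluster distance** is the VMval between representatives —
  "smallest distance" needs a definition and the voltage mismatch is the
  one already computed.
* **Directed input** is carried by the data model; circuits symmetrize
  conductance (antiparallel edges add, as parallel resistors do) while
  PMval compares the directed adjacency. The voltage signature is weaker
  for directed graphs; the stage-3 enumeration remains exact.

## Clustering

Candidates are the connected, non-tree (edge count ≥ node count) k-node
induced subgraphs, enumerated exactly by the ESU scheme: node v only
extends to higher-indexed neighbours not adjacent to the current subset, so
every connected subset is produced exactly once, from its minimum-index
node. Induced semantics is the standard motif convention.

Clustering is two-phase. Phase 1 repeatedly pairs cluster i with cluster
i + ⌈L/2⌉ (L = current cluster count; the middle element of an odd list is
carried unchanged — the stride pairing does not define odd behaviour, so
the leftover is simply kept) and merges pairs that pass the isomorphism
test, until a pass makes no merge. The long stride keeps successive
comparisons between previously distant clusters. Phase 2 agglomerates the
residue: repeatedly merge the passing pair with smallest VMval until none
passes. Memory stays linear in the number of active clusters — no n×n
distance matrix exists at any point, which is what makes the method usable
on large candidate sets. Support is conserved at every step (asserted as an
invariant), indices are re-compacted between passes, and the whole pipeline
is deterministic: identical input, configuration and seed give
byte-identical JSON reports.

## The synthetic generator

`random_probability_network()` emulates the relevant features of a sparse
uncertain interaction network: n nodes, a fixed total edge budget, edge
probabilities from a uniform (default, on [0.5, 1] — confidence-scored
interactions are usually reported above 0.5) or truncated beta law, and
optionally `copies` disjoint planted copies of a pattern whose edge
probabilities are jittered by at most `jitter` and clipped to [0.01, 1]
(the floor keeps the open interval (0, 1] of the model intact). Background
edges avoid pairs internal to a planted copy, so every planted instance is
an exact induced occurrence and ground truth is unambiguous.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: power-law degree distributions, correlated edge
probabilities, overlapping pattern occurrences, directed regulatory
structure, and measurement-specific noise models. Recovery results on
planted patterns demonstrate correctness of the machinery, not performance
on any particular organism's network.

## Numerical choices and problem sizes

Voltage systems are solved densely (`solve()`); subgraphs have k ≤ 8 nodes,
so stability is not a concern, and the reduced matrix is well conditioned
for probabilities bounded away from 0. Comparisons involving VMval use an
absolute tolerance of 1e−9. Ascending sorts are stable; assignment ties are
resolved deterministically by the solver; the stage-3 search is
lexicographic with early exit.

The test and acceptance workloads are sized for quick, deterministic runs
on one CPU: benchmark voltages on the 4-node graph; 100 relabelled-copy and
100 different-topology pairs at k = 3–5 for the exact special case; 200
pairs × 4 thresholds against the exhaustive oracle; 100 random 6×6
assignment problems; and 20 generator seeds of a 40-node, 60-edge host with
6 planted 4-node copies (jitter 0.01) for recovery, reported as successful
runs out of 20.

## Limitations

* The voltage filter is necessary, not sufficient; correctness of accepts
  rests on the PMval stages. Highly symmetric graphs admit many optimal
  mappings and may push pairs into the factorial stage (capped, with an
  explicit refusal, at `max_permutation_k`).
* Frequent patterns are not motifs: significance against randomized
  networks is a separate step outside this package's scope.
* Tree-shaped patterns are excluded by design; approximate (sampled)
  enumeration is not implemented.
* Node labels (protein identities) are carried through reports but play no
  role in isomorphism — patterns are positional, as in standard motif
  analysis.
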