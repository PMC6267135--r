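---
title: "An influence spreading model for network centrality, cohesion and community detection"
author: "spreadnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An influence spreading model for network centrality, cohesion and community detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadnet)
```

## The model

`spreadnet` computes, for every ordered pair of nodes $(s, t)$ of a directed
or undirected network, the probability $C_{s,t}(T)$ that an influence process
started at $s$ at time $0$ has reached $t$ by time $T$.  Three ingredients
define the model:

1. **Temporal spreading.**  Each node that receives influence forwards it to
   each neighbour after a random delay.  With Poisson intensity $\lambda$ per
   unit time, the probability that influence has advanced at least $L$ hops
   along a chain by time $T$ is the Poisson tail
   $$D_L(T) = P(K(T) \ge L) = 1 - \sum_{z=0}^{L-1} e^{-\lambda T}
   \frac{(\lambda T)^z}{z!}, \qquad D_0(T) = 1 ,$$
   equivalently the CDF of a Gamma$(L, \lambda)$ first-passage time.  Both
   formulations are implemented and cross-checked in the tests.  Any
   empirical delay table can replace the Poisson family
   (`empiricalModel()`); it is validated against the defining invariants
   ($D_L$ nondecreasing in $T$, nonincreasing in $L$, $D_0 = 1$,
   $D_{L \ge 1}(0) = 0$).

2. **Node and link activities.**  A path of length $L$ from $s$ to $t$
   carries probability
   $$C = w_{N=t} \, W_L \, D_L(T), \qquad
   W_L = \prod_{j} w_N(I(j)) \; w_L(I(j), I(j+1)),$$
   the product running over the path's links and over every node after the
   source; the source itself always has activity 1 (it initiates the
   process).  All weights live in $[0, 1]$.

3. **Prefix-dependent combination.**  All self-avoiding paths (or,
   optionally, bounded walks) from $s$ of at most $L_{max}$ links are
   enumerated depth-first and organised per target into a prefix trie.
   Paths sharing their initial links are statistically coupled through the
   shared prefix; branches that separate are treated as independent
   attempts.  The trie is evaluated bottom-up: a terminal node has
   conditional value $q = 1$, and an internal node at depth $L$ with
   endpoint $m$ and children $m_i$ has
   $$q = 1 - \prod_i \Big( 1 - w_L(m, m_i) \, w_N(m_i) \,
   \frac{D_{L+1}(T)}{D_L(T)} \, q_i \Big),$$
   with $C_{s,t}(T) = q(\mathrm{root})$.  The factor $D_{L+1}/D_L$ is the
   conditional probability of one further hop given $L$ hops completed; its
   telescoping product along a chain recovers $D_L(T)$ exactly.

### Why the conditional recursion is normative

The classical presentation of the two-route case combines absolute path
probabilities as $P_{L_1} + P_{L_2} - P_{L_1} P_{L_2} / P_L$, dividing by the
probability of the shared prefix.  That division form is algebraically
equal to the conditional form only when the junction node's activity is 1,
and it is undefined at $T = 0$.  The package therefore uses the conditional
recursion everywhere (it is well defined for all weights and all $T$, and
multi-way branching $1 - \prod(1 - r_i)$ is the associative closure of the
iterated pairwise rule), and retains the literal pairwise-division algebra
as an *independent oracle* (`pairwiseReference()`), valid exactly in the
unit-activity regime, where the two routes agree to $10^{-12}$ on every
tested instance.

### A property the model does not have: symmetry

Prefix dependency is anchored at the source.  On an undirected graph with
uniform weights, reversing all paths changes which links are shared: a
"diamond on a stem" gives $C_{s,t} = 2D_3 - D_3^2/D_1$ from the stem side
but $C_{t,s} = 2D_3 - D_3^2$ from the fork side.  The influence matrix of a
symmetric network is therefore *not* symmetric in general (on the bundled
worked-example subgraph the maximal asymmetry is $\approx 0.04$ at
$\lambda = T = 1$), and no symmetry is asserted anywhere in the package.

### Walks mode

The loop-allowing variant enumerates bounded walks instead of self-avoiding
paths.  A walk may revisit intermediate nodes (self-links are excluded by
the network invariant), but a path to target $t$ is recorded only at the
first arrival: influencing $t$ is a first-passage event, so re-traversals
through the target add nothing.  Walk enumeration is implemented as
straightforward bounded depth-first search; the memory-optimised streaming
variant used for very large networks elsewhere in the literature is out of
scope here.

## Measures on the influence matrix

With the diagonal convention $C_{n,n} = 1$:

* **Closeness.** $C_{n,\cdot} = \sum_j C_{n,j}$ (out) and
  $C_{\cdot,m} = \sum_i C_{i,m}$ (in), normalised versions divide by $N$.
  Including the self term makes every centrality curve start at 1 at
  $T = 0$ and keeps isolated nodes at the constant value 1.
* **Cohesion.** $C = \frac1N \sum_{i,j} C_{i,j}$, the network-level average;
  the grand-total identity $\sum_n C_{n,\cdot} = \sum_m C_{\cdot,m} = N C$
  holds exactly and is asserted in the tests.
* **Removal betweenness.** $B_n = \frac1N \sum_{i,j \ne n} C^{(-n)}_{i,j}$,
  recomputed on the node-deleted network but normalised by the *original*
  $N$; $R_n = B_n / C$ and $b_n = 1 - R_n$.  This normalisation, together
  with subgraph monotonicity (deleting a node can only remove paths), keeps
  $b_n \in [0, 1]$ provably.
* **Geodesic baselines.** Reciprocal closeness, its gradient variant with
  exponent $\delta$, and shortest-path betweenness with the
  $(g_{jk}-1)^{-\delta}$ weighting, for comparison with purely structural
  measures.  Unreachable pairs contribute 0 (including at $\delta = 0$);
  adjacent pairs are excluded from the $\delta$-weighted betweenness, whose
  value at $g_{jk} = 1$ is otherwise undefined.

## Community detection

Two factions $V, \bar V$ are scored by the intra-influence objective
$$P(V, \bar V) = \sum_{s,t \in V} C_{s,t} + \sum_{s,t \in \bar V} C_{s,t},$$
computed on the matrix with its diagonal zeroed -- the diagonal only shifts
$P$ by a constant, and the zero convention makes $P \le S_{total}$ (total
off-diagonal influence) with equality exactly when no influence crosses the
boundary.  Local search sweeps the nodes in ascending index order and moves
a node only on *strict* improvement; restart search deduplicates the local
maxima found and ranks them by $P$ (the rank is the community identifier).

Two design points deserve emphasis:

* **The trivial division is the reference, not a community.**  Putting all
  nodes into one faction attains $P = S_{total}$, the global optimum by
  construction, and local search converges there from many starts.  A
  division with an empty faction is therefore reported as the whole-network
  reference value and excluded from the catalog; the rank-1 entry is the
  best *proper* division.
* **Degenerate ties collapse.**  Distinct compositions whose $P$ agree
  within $10^{-9}$ are treated as one entry, so a network with a flat
  objective (e.g. an edgeless one, where every split ties at $P = 0$)
  yields a single catalog entry instead of one per restart.

Refinement (`refineWithIntersections()`) seeds further local searches from
set differences of nested factions and intersections of overlapping ones --
such sets are natural sub-community candidates -- and iterates until no new
composition appears, which makes re-running it a no-op.  Faction sizes
exclude isolated nodes; `relationsReport()` lists nesting, exact
union/intersection identities, and genuine overlaps among the detected
factions.

## Validation oracles

* `pairwiseReference()` -- the independent algebraic route described above.
* `simulateSpread()` -- a Monte-Carlo event simulation of the process
  itself: per replicate, each link carries an exponential$(\lambda)$
  forwarding delay gated by a Bernoulli$(w_N \cdot w_L)$ acceptance, and a
  node's influence time is its first arrival (a replicate-vectorised
  random-weight shortest path).  On chains and trees there is a unique path
  per node, so the estimate converges to the analytic $C_{s,t}$; this is
  asserted statistically in the tests.  On graphs with re-merging paths the
  analytic model's prefix-only dependency treatment is an approximation to
  the simulated process, so there the deviation is only reported, never
  asserted.

A note on the statistics of stochastic checks: an ensemble of hundreds of
binomial comparisons will exceed a per-comparison $3\sigma$ band somewhere
with high probability even when the model is exact.  The unit suite
therefore validates oracle agreement with multiplicity-aware aggregates
(mean squared $z$ near 1, no systematic bias, worst $|z|$ under a
Bonferroni-level bound) rather than a simultaneous per-node band.

## Parameters, defaults and problem sizes

| parameter | meaning | default / typical |
|---|---|---|
| $\lambda$ | forwarding intensity per unit time | no default; required |
| $T$ | evaluation time; $\lambda T$ is the maturity of the process | per analysis |
| $L_{max}$ | maximum path length (links) | 6; 4--10 useful, tails beyond ~20 negligible |
| mode | self-avoiding paths / bounded walks | self-avoiding |
| $w_N$ | node activity (forwarding probability) | 1; 0.5 models weak ties |
| $w_L$ | per-link weight | 1 |
| diagonal | self value $C_{n,n}$ | 1 (0 for community work) |

The synthetic generators emulate the test topologies: chains and random
recursive trees (where the model is exact and simulation can certify it),
connected sparse random graphs (edge probability $p$, augmented with
bridging links until connected -- at $p = 0.05$ and $n = 32$ this yields a
near-tree with mean degree $\approx 2$, typical of sparse social networks),
and planted two-block graphs for community recovery.  They do not emulate
degree heterogeneity, clustering, or assortativity of real social networks,
so passing tests certify the *model semantics*, not sociological realism.

Suite problem sizes were chosen to keep the full run at around a minute:
9-node worked example, 6--8 node randomized instances for the property
suites, a 32-node network for the saturation limit
($C_n \to N$ at $\lambda T = 200$, $L_{max} = 31$), 16-node planted graphs
(with exhaustive enumeration of all $2^{15}$ splits as the ground truth),
and 50 random trees at $2 \times 10^5$ simulation replicates for the
stochastic validation.

## Numerical choices and edge cases

* The per-hop factor at $T = 0$ (where $D_L = 0$ for $L \ge 1$) is defined
  as 0: no spreading happens in zero time, and the recursion never divides
  by zero.
* Node labels are arbitrary; internally nodes map to a dense index (numeric
  order when all labels are integer literals, radix order otherwise), and
  neighbour expansion is in ascending index order, making enumeration and
  every downstream report deterministic.  Ranking ties are dense and listed
  in label order.
* Unreachable pairs evaluate to 0; an empty path set gives an empty trie
  with value 0.
* Duplicate links with conflicting weights are rejected; self-links are
  rejected everywhere.
* The empirical temporal family interpolates linearly in $T$ (anchored at
  $(0, 0)$ for $L \ge 1$, constant beyond the table) and evaluates to 0
  beyond its largest tabulated $L$.

## A worked example

The bundled 9-node subgraph spans the 14 self-avoiding paths between two
reference nodes; all of them pass through one gateway node, so the prefix
trie has a single root branch:

```{r}
net <- workedExampleNetwork()
paths <- enumeratePaths(net, "1", lMax = 8)[["4"]]
length(paths)
range(lengths(paths) - 1L)

p <- spreadParams(poissonModel(1), time = 1, lMax = 8)
evaluateTrie(buildPathTrie(paths), net, p)
pairwiseReference(paths, net, p)   # independent algebra, same value
```

## Known limitations

* Exact enumeration scales with the number of bounded(-length) paths;
  dense graphs need small $L_{max}$.  The streaming large-network algorithm
  referenced in the literature is deliberately out of scope.
* On non-tree graphs the model is a defined semantics, not an unbiased
  estimate of the simulated cascade; deviations grow with the density of
  re-merging path structure.
* State-dependent propagation (nodes forwarding only novel information) and
  estimation of $\lambda$ from data are out of scope; a uniform-delay
  temporal family is not provided because no defining table for it is
  fixed -- the empirical interface accepts any user-supplied one.
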