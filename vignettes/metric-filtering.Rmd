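---
title: "Metric filtering of chromosome conformation graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric filtering of chromosome conformation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformet)
```

## The problem

Chromosome conformation capture (3C/4C/Hi-C) experiments measure, across
millions of cells, how often pairs of genomic restriction fragments are
spatially proximal. Each interaction between fragments carries a frequency,
which a calibration curve converts into a spatial distance `d(e)`, and a
statistical confidence `r(e)` (conventionally `1 - q` for an FDR-adjusted
q-value). Because the measurements aggregate a heterogeneous cell
population, the resulting distances are frequently *metrically
inconsistent*: a large fraction of fragment triplets fails the triangle
inequality, which makes 3D reconstruction ill-posed.

`conformet` treats interaction filtering as a constrained selection
problem: among all interactions, keep a subset of maximum total confidence
whose distances are mutually consistent.

## The consistency model

An edge `e` with endpoints `{a, b}` is **k-consistent** in a subset `S` if
every path of at most `k` edges inside `S` joining `a` and `b` is at least
as long as `d(e)`. Equality is consistent; only a *strictly* shorter
bypass violates. Two named special cases matter:

* **ConsT** (`k = 2`): every retained triangle obeys the triangle
  inequality. The lenient end of the family, appropriate when summed
  distances accumulate error quickly.
* **ConsP** (`k = |V| - 1`): every retained edge is a shortest connection
  between its endpoints — a true metric subgraph. The strict end.

The optimization problem — maximize `R(S) = sum_{e in S} r(e)` subject to
consistency — is NP-hard for every `k >= 2` (by reduction from Independent
Set; the reduction graph is available as `independent_set_gadget()` and
its defining property is verified exhaustively in the test suite).

### Uncertain distances

A measured frequency more plausibly maps to a *range* of distances
`[l(e), u(e)]` than to a point value. The ranged condition declares `e`
violated only when some `<= k`-hop path has summed *upper* bounds below
`e`'s *lower* bound. The slack factor `rho` in `consistency_spec()`
generates symmetric ranges `l = (1 - rho) d`, `u = (1 + rho) d`:
`rho = 0` recovers the strict condition, and at `rho = 1` the lower bound
hits zero, so nothing can be violated and every filter becomes the
identity. Violation sets shrink monotonically as `rho` grows (a property
the acceptance suite checks on a 0-to-1 grid in steps of 0.01). Explicit
per-edge ranges stored on the graph take precedence over `rho`.

## Algorithms

Three algorithms target ConsT:

* `setcover_greedy()` casts triangle repair as minimum-weight set cover —
  removing edge `e` at cost `r(e)` "covers" every violated triangle
  containing it — and applies the classical greedy rule (cost per newly
  covered triangle; a `rule = "cost"` variant branches on plain cost,
  since the greedy score is not pinned down by the set-cover literature
  alone).
* `setcover_fapprox()` solves the fractional covering relaxation and
  removes every edge with value `>= 1/3`. Each violated triangle has at
  most three member edges, so this rounding always covers, at cost at
  most 3 times the optimal removal cost (the classical f-approximation
  with f = 3).
* `maxcut_hierarchical()` keeps a reward-weighted local max cut (bipartite,
  hence triangle-free), deletes same-side edges that close violated
  triangles with two cut edges, and recurses into both sides. The
  single-move local search in `maxcut_local()` terminates at a partition
  where every vertex has at least half its incident reward in the cut, so
  the first cut alone carries at least half the total reward.

Two target ConsP:

* `sp_union()` keeps exactly the edges lying on some shortest path between
  their endpoints (removal when the shortest-path length is strictly below
  the edge's own length; in ranged mode path lengths use `u` and the
  threshold is `l`).
* `mst_add()` grows a maximum-reward spanning forest (Kruskal,
  lexicographic tie-breaks) and re-adds remaining edges in descending
  reward order whenever the growing set stays all-paths consistent.

`ilp_exact()` certifies the ConsT optimum on small instances by exhaustive
branch-and-bound over violated-triangle hitting sets (an `"enumerate"`
mode scans all subsets outright; both are exact and are cross-checked
against each other and against an independent enumeration oracle in the
tests). `lp_upper_bound()` solves the linear relaxation of the selection
integer program — maximize fractional reward subject to
`x_e1 + x_e2 + x_e3 <= 2` per violated triangle — whose objective bounds
every consistent subset from above. `crank()` is the baseline that keeps
the `m` most confident edges regardless of geometry.

## Embedding and evaluation

`embed_graph()` places fragments in 3D by minimizing the stress
`sum_e (o(e) - d(e))^2` (realized minus assigned distance) with L-BFGS-B
and an analytic gradient, from a seeded isotropic Gaussian initialization
scaled to the mean edge length. This is deliberately *pure* stress
minimization: chromatin-packing or nuclear-volume constraints used by
full-genome reconstruction pipelines are out of scope, so absolute error
magnitudes are not comparable with published full-pipeline values — only
orderings and trends are.

Filterings are evaluated by:

* the mean stress across an `embed_ensemble()` of seeded restarts, and
* `ensemble_variability()`: the total branch length of the minimum
  spanning tree of the complete graph on structures weighted by pairwise
  superposed RMSD — a parsimonious summary of how sensitive the embedding
  is to initial conditions.

`reintroduce_violations()` inverts the filtering logic for validation: it
repeatedly picks a random triangle `{u, v, w}` (roles in lexicographic
node order) and shrinks one edge to `alpha * |d(v,w) - d(u,w)|`
(`0 < alpha < 1`), manufacturing violated triangles at a requested rate so
the error-versus-violations trend can be measured on ground-truth data.

### Chirality

The stress objective depends on coordinates only through pairwise
distances, so it is invariant under the full orthogonal group: independent
restarts may converge to mirror-image structures that realize identical
distances. `superpose()` therefore defaults to proper rotations (Kabsch),
as structure comparison conventionally does, but `ensemble_variability()`
quotients out reflections by default — variability of a chirality-blind
estimator should not count the arbitrary hand of each restart as signal.
Coordinate-recovery tests compare planted and estimated structures modulo
reflection for the same reason.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `k` | 2 | hop budget of the consistency condition; `"all"` for ConsP |
| `tolerance` | 1e-9 | relative float tolerance; a path must undershoot its threshold by more than `tolerance * max(1, threshold)` to violate. Boundary equality is consistent (the defining inequality is non-strict) |
| `rho` | none | slack factor in [0, 1]; `l = (1-rho) d`, `u = (1+rho) d` |
| `alpha` | 0.9 | violation-injection shrink factor |
| `edge_density` | 1 | fraction of fragment pairs connected by the generator |
| `noise_sd` | 0 | log-normal sd of multiplicative distance noise |
| `reward_scale` | 5 | slope of the synthetic confidence decay `r = 1 / (1 + scale * relative error)` |
| `seed` | 0 | every randomized routine takes one and is bit-reproducible given it |

## Numerical choices

* **Tie-breaking.** All order-dependent steps (greedy picks, Kruskal,
  C-Rank, the hierarchical cut-pair scan) break ties by cost and then by
  lexicographic edge order under C collation, so results do not depend on
  locale or input row order. Deletions made at an outer recursion level of
  the hierarchical cut are permanent.
* **Witness paths.** When testing edge `e`, paths may use any edge except
  `e` itself (a one-hop "path" equal to `e` would be vacuous). With
  nonnegative lengths, simple paths dominate walks, so hop-limited
  Bellman-Ford relaxation (finite `k`) and Dijkstra (`k = |V| - 1`) are
  exact; both routes are tested for equality against explicit path
  enumeration.
* **LP back-end.** Small LPs are solved exactly with a dense tableau
  simplex (`boot::simplex`); instances with more than ~150 variables
  switch to a dual active-set quadratic program with a ridge of 1e-6
  (relative) on the objective. The regularized point is always feasible;
  its objective is accurate to well below the 1e-6 constraint tolerance
  used by the rounding rule, though on large instances the reported LP
  bound is correspondingly approximate rather than exact.
* **Optimizer.** `factr` for L-BFGS-B is derived from `tol` (default
  1e-12 relative); line-search aborts with a vanished gradient — which
  occur in the flat rigid-motion directions of the stress — are treated
  as convergence. Non-converged embeddings return the best iterate with a
  warning flag.
* **Degeneracies.** Violation injection clamps a zero-length assignment
  (`d(v,w) = d(u,w)`) to 1e-6 to preserve positive lengths; additive
  Gaussian generator noise is clamped the same way. Disconnected graphs
  are legal everywhere: unreachable endpoints impose no constraint, and
  spanning "trees" become forests.

## What the synthetic benchmarks do and do not show

The generator plants points uniformly in a unit cube, connects a random
fraction of pairs, perturbs true distances multiplicatively (log-normal,
so lengths stay positive), and assigns confidences that decay with the
relative measurement error. The benchmark conditions used in the
acceptance experiments — 15 fragments, edge density 0.7, noise sd 0.3,
10 embeddings per filtering — are chosen to emulate the regime of real
chromosome conformation graphs: dense interaction maps in which roughly
30% of measured triplets violate the triangle inequality (noise sd 0.3 at
density 0.7 reproduces that violated fraction on planted graphs).

Synthetic graphs differ from real 4C data in ways that matter for
interpretation: confidences here are a clean monotone function of the
per-edge error, whereas real q-values are noisy statistical summaries;
real frequency-to-distance calibrations are nonparametric and
heteroskedastic (the built-in power law `f = c * d^-gamma` is a
parametric stand-in); and population aggregation in real data mixes
*distinct* structures rather than perturbing one. Passing tests therefore
demonstrate the algorithmic guarantees (consistency of outputs,
approximation ratios, bound ordering) and the *direction* of the
embedding-quality effects, not the error magnitudes reported for any
particular organism.

Test problem sizes are deliberately desk-scale: guarantee sweeps use 200
graphs of 6-40 fragments, optimality sandwiches 100 instances of at most
20 edges, gadget equivalence is exhaustive over all graphs on up to 5
nodes, and the embedding experiments use 10-15 fragments with 2-10
restarts.

## Known limitations

* The stress optimizer finds local minima; ensembles over seeds mitigate
  but do not eliminate this, and severely violated inputs have genuinely
  frustrated landscapes (that frustration is what the error statistic
  measures).
* The LP bound on instances beyond the exact-simplex threshold carries the
  regularization error described above (~1e-6 relative).
* Optimization algorithms are provided for the two named problems
  (`k = 2` and `k = |V| - 1`) only; consistency *checking* supports any
  `k >= 2`.
* `superpose()` warns and returns a best fit for degenerate (fewer than 3
  non-collinear points) configurations rather than failing.
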