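# conformet

Metric filtering and 3D embedding of chromosome conformation graphs.

Chromosome conformation capture assays (3C/4C/Hi-C) measure how often pairs
of genomic restriction fragments are spatially close in a population of
cells. Mapping interaction frequencies to spatial distances gives a weighted
graph — fragments as nodes, interactions as edges with a distance `d(e)` and
a statistical confidence `r(e) = 1 − q(e)` — but population averaging makes
these distances *metrically inconsistent*: many fragment triplets violate
the triangle inequality, which frustrates 3D reconstruction. `conformet` is
for researchers who want to filter such graphs on **both** statistical
confidence and metric consistency before embedding them.

## The optimization problem

Given `G = (V, E)` with nonnegative lengths `d(e)` and positive rewards
`r(e)`, and an integer `k ≥ 2`, find `S ⊆ E` maximizing

```
R(S) = Σ_{e∈S} r(e)
```

such that for every `e ∈ S` and every path `P` of at most `k` edges in `S`
joining the endpoints of `e`,

```
Σ_{e′∈P} d(e′) ≥ d(e).
```

`k = 2` (**ConsT**) enforces the triangle inequality on retained triangles;
`k = |V| − 1` (**ConsP**) demands a true metric subgraph. The problem is
NP-hard for every `k ≥ 2`, so the package provides approximation algorithms
and heuristics plus an LP relaxation whose objective upper-bounds the
optimum. With uncertain distances, each edge carries a range `[l(e), u(e)]`
(e.g. `l = (1−ρ)d`, `u = (1+ρ)d` for a slack factor `ρ`) and a path
violates only when its summed upper bounds fall below the edge's lower
bound.

Algorithms: `setcover_greedy()` and `setcover_fapprox()` (minimum-weight
set cover over violated triangles; the LP rounding is a 3-approximation of
the removal cost), `maxcut_hierarchical()` (recursive reward-weighted max
cut, ≥ ½ of total reward), `sp_union()` and `mst_add()` (ConsP),
`ilp_exact()` (certified optimum on small instances), `lp_upper_bound()`,
and the confidence-only baseline `crank()`. Filtered graphs are embedded by
stress minimization (`embed_graph()`, objective `Σ (o(e) − d(e))²`) and
evaluated by embedding error and by the minimum-spanning-tree variability
of an ensemble of restarts (`ensemble_variability()`).

## Worked example

```r
library(conformet)

pl <- planted_graph(15, edge_density = 0.7, noise_sd = 0.3, seed = 42)
g  <- pl$graph
g
#> conformation graph: 15 fragments, 74 interactions
#>   d in [0.08805, 1.759], total reward 42.14

spec <- consistency_spec(k = 2)
find_violations(g, spec)
#> violation set: 23 violated edge(s), 37 witness entries
#>   violated triangles (k = 2): 37

fr <- setcover_greedy(g, spec)
fr
#> setcover-greedy filtering: kept 57 / 74 edges, total reward 34.6326

lp_upper_bound(g, spec)
#> LP relaxation: objective 35.7289 over 74 edges (37 triangle constraints)

compare_filterings(g, "setcov", "crank-matched", spec = spec,
                   n_restarts = 10, seed = 42)
#> setcover-greedy         57 edges  mean error 0.18828  variability 1.22095
#> crank                   57 edges  mean error 0.218622  variability 0.771124
```

Reading the numbers: 37 of the graph's triangles violate the triangle
inequality; the greedy set-cover filter removes 17 edges to repair all of
them while keeping total confidence 34.63 of a fractional upper bound of
35.73, i.e. within 3% of anything any consistent filtering could achieve.
Embedding the filtered graph ten times yields a lower mean stress (0.188)
than a confidence-ranked baseline of identical size (0.219): the metric
filter discards the edges whose distances cannot be realized in 3D, which
confidence ranking has no way to see. Ensemble variability fluctuates from
instance to instance at this problem size.

A command-line wrapper over the same functions is installed at
`inst/cli/conformet.R`:

```sh
Rscript inst/cli/conformet.R simulate --nodes 30 --seed 1 --out edges.tsv
Rscript inst/cli/conformet.R filter --algorithm setcov --input edges.tsv \
    --output kept.tsv --report report.json
Rscript inst/cli/conformet.R embed --input kept.tsv --out coords.tsv --restarts 10
```

Edge lists are TSV with columns `fragment_a`, `fragment_b`, `distance`
and/or `frequency`, `confidence`, optional `lower`/`upper`; see
`?read_edges`.

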