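---
title: "Modelling two-stage health care access and POCT placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-stage health care access and POCT placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpath)
```

## The model

`scpath` models access to emergency (cardiac) care in a rural health system
as a *spatial care path*: a patient at populated place $i$ first travels to
the nearest facility holding point-of-care diagnostic technology (POCT),
and only after diagnosis travels on to the single tertiary care center $c$
where definitive treatment exists. Over a road network with travel-time
edge weights $t(\cdot,\cdot)$, the path for origin $i$ given the set $S$ of
POCT-equipped sites is

$$ d(i) = \arg\min_{s \in S} t(i, s), \qquad
   T_i = \underbrace{t(i, d(i))}_{\text{to diagnosis}} +
         \underbrace{t(d(i), c)}_{\text{to care}} . $$

The first stage is deliberately greedy — the patient travels to the
*closest* diagnosis, not the one minimizing the eventual total — because
that is how closest-facility routing behaves and how patients without
global knowledge of the network act. The model makes the detour cost of
that behaviour visible: $T_i \ge t(i, c)$ always, and the inequality is
strict whenever the nearest POCT site lies away from the care center (the
"backtracking" phenomenon; `backtracking_region()` constructs a minimal
network certifying it).

Population access is the demand-weighted mean of each stage,

$$ \bar T = \frac{\sum_i w_i T_i}{\sum_i w_i}, $$

with $w_i$ the place population. Policy scenarios are compared through the
percent decrease $100\,(\bar T_{\text{current}} - \bar T_{\text{alt}}) /
\bar T_{\text{current}}$, rounded to one decimal.

### Assumptions

* Travel is by road only, at a fixed speed per road class; no congestion,
  time-of-day effects, or one-way restrictions. The network is undirected
  and turns are free at every junction.
* Every patient takes the fastest route and chooses the nearest POCT site
  (ties broken by facility id, so results are deterministic).
* The care center always counts as a permissible diagnosis site: a patient
  who reaches the tertiary hospital is diagnosed there. Anything else would
  route patients already at definitive care back out of it.
* Coordinates are planar meters (inputs are assumed already projected, e.g.
  UTM); no geodesy is performed.

## Network construction

Raw road polylines become a routable graph in `build_network()`:

1. All polyline vertices within the snap tolerance (default **10 m**) are
   merged into shared junctions by single-linkage clustering, emulating the
   GIS "integrate" step that makes crowd-sourced road data connective.
2. Polylines are split at merged vertices, so roads crossing at a shared
   vertex become mutually traversable. Zero-length leftovers are dropped
   with a warning.
3. Each segment's travel time is
   $\text{minutes} = 60 \cdot (\text{length}_m / 1609.344) / \text{mph}$,
   with the class speed from `speed_table()` (65 mph trunk down to 15 mph
   service roads). Unknown classes are an error, never a silent default, so
   data problems surface at read time.

Off-network points — places and facilities — are attached by
`connect_point()`: a straight **connector** edge (class `connector`,
35 mph) to the nearest point on the nearest segment, which is split at the
foot so routing through the connector is exact. Total network length is
conserved by the split. Ties between equidistant segments go to the
smallest segment id. Whether the original analysis split the target road
or merely touched it is not documented; we split, because routing is
otherwise wrong at exactly the junctions that matter, and note this as a
divergence risk for exact replication.

## Access summaries

`summarize_access()` reports mean and SD per stage, population-weighted or
not. The weighted SD normalizes weights to mean one,
$w_i' = n w_i / \sum w$, and uses the sample form
$\sqrt{\sum_i w_i' (T_i - \bar T)^2 / (n - 1)}$. This convention was chosen
over raw frequency weights (population as replication count) because it
satisfies an invariant we consider non-negotiable: any *equal* weighting
must reproduce the unweighted summary exactly, whatever the common
population value is. Unreachable origins are excluded with a warning
rather than failing, so partial networks remain analyzable; `n_routes`
reflects the exclusion. Travel-time distributions are reported as
left-closed 15-minute bins (`histogram_15min()`).

Whether the published comparison tables were population-weighted is
ambiguous in one cell: recomputing the "rearrange" strategy's total
percent decrease from its printed means gives 17.2 %, not the printed
16.7 %, while every other cell reproduces exactly.
`reference_tables()` flags that row (`consistent_total = FALSE`) and the
parity checks assert the arithmetically consistent value rather than
guessing the original weighting.

## POCT placement as a constrained P-median

The limited-resource strategies select $k$ POCT sites minimizing
population-weighted time to diagnosis, with an optional *required* subset
forced into the solution:

* `rearrange` — free relocation of the existing units ($R = \emptyset$,
  $k = |P_0|$);
* `keep_plus_k` — existing units pinned, $k_\text{extra}$ added
  ($R = P_0$, $k = |P_0| + k_\text{extra}$);
* `rearrange_plus_k` — the relaxation of the above ($R = \emptyset$, same
  $k$), which can never do worse.

Two solvers share the problem object. `solve_exact()` enumerates all
$\binom{|C \setminus R|}{k - |R|}$ subsets (capped, default 200 000) and is
the oracle. `solve_heuristic()` is a greedy start plus Teitz–Bart vertex
substitution: repeatedly apply the best strictly improving single swap
until none exists, over `n_restarts` starts (first greedy, rest random),
deterministic under its seed. The swap evaluation uses best/second-best
bookkeeping per demand row, the standard acceleration. The heuristic's
objective is an upper bound on the optimum by construction; on the shipped
`known_optimum_fixture()` (8 candidates, enumerable) it attains the frozen
brute-force optima for every $k \le 4$ and every strategy variant. Ties —
between subsets in the exact solver, and in nearest-site assignment — break
lexicographically by id. The objective is stage-1 time by default;
`optimize_poct(objective = "total")` instead minimizes time to diagnosis
plus onward time to care, the refinement suggested by the backtracking
phenomenon. Impedance is linear with no cutoff, the simplest reading of an
otherwise undocumented solver configuration.

## The synthetic generator

The real inputs (a 2014 OSM Thailand extract, proprietary facility points,
an unpublished POCT survey) are not redistributable, so
`generate_region()` emulates their structure instead:

* **Road network** — a square grid (default) or a random planar graph.
  Random planar networks are Gabriel graphs (an edge survives iff the
  circle on its diameter is empty) with random thinning that preserves
  connectivity; Gabriel graphs are connected planar subgraphs of the
  Delaunay triangulation and need no triangulation dependency. Any
  connected mixed-class planar graph serves the property tests equally.
* **Places** — types drawn from the published mixture (1 city : 1 suburb :
  5 towns : 1303 villages : 83 hamlets), each carrying its default
  population (city/suburb 100 000, town 20 000, village 10 000, hamlet
  200); positions are road-adjacent with a 50–800 m offset so connector
  logic is always exercised.
* **Facilities** — default 44 hospitals and 347 health promoting
  hospitals, the published provincial totals; sited at junctions sampled
  proportionally to local place density, echoing the observed clustering
  of facilities near populations. The care center is the hospital farthest
  by network time from the population-weighted centroid place, emulating a
  tertiary destination outside the population core.
* **Current POCT** — 14 hospitals. The surveyed roster's size was never
  published; 14 is a fixed free parameter of the generator, not a
  published value.

Default problem size is 300 places on a 900-junction grid — about a fifth
of the real region's 1393 places, chosen so the full pipeline (network
build, all eight scenarios, five heuristic optimizations) completes in
about a minute while keeping every structural feature. The generator is
deterministic under `config$seed` and restores the caller's RNG state.

What the generator does **not** emulate — and what passing tests therefore
do not establish about the real region: true road geometry and class
frequencies, the spatial autocorrelation of Thai settlement patterns,
population heterogeneity within a place type, and the actual surveyed POCT
locations. Parity with the published numbers rests on the printed tables
as inputs, not on regenerating Thailand.

## Numerical choices

* Units: meters and minutes internally; speeds stay in mph as published
  and convert at 1 mile = 1609.344 m.
* Comparisons in snapping, tie-breaking and optimality use a 1e-12
  absolute guard; percent cells and table means round to one decimal only
  at the reporting edge (percent decreases are computed from unrounded
  means, then rounded).
* Degenerate inputs: a point coinciding with a junction attaches directly
  (no zero-length connector); a point on a segment interior splits it and
  attaches at the foot; empty connector sets report zeros with an `empty`
  flag; an empty time vector yields an empty histogram.
* `solve_exact` refuses problems past its enumeration cap with a pointer
  to the heuristic rather than silently running for hours.

## Limitations

Pure closest-facility logic: no capacity constraints, no probabilistic
choice, no gravity/floating-catchment accessibility indices. One care
destination. No turn costs or one-way modelling. Map rendering of results
is out of scope; outputs are tables (CSV with a metadata header) and the
histogram counts.
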