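---
title: "Methods: fairness-efficiency optimization of emergency PPE distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fairness-efficiency optimization of emergency PPE distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppealloc)
```

## The decision problem

During a fast-spreading infectious-disease outbreak, personal protective
equipment (PPE) stored in a handful of reserve centers must reach affected
areas through rented distribution centers (DCs), under vehicle fleets,
stock levels, DC capacities and a coverage radius that caps how far any
vehicle may drive.  Supply is typically short of demand, so the planner
faces a genuine fairness-efficiency conflict: serving nearby areas quickly
is efficient, while spreading scarce stock to remote, hard-hit areas is
fair.

`ppealloc` resolves that conflict with a single loss objective built on the
victims' *bearing capacity*.  The per-kilogram cost of waiting $t$ seconds
for PPE type $k$ is

$$\lambda_k(t) = \begin{cases} a_k\,t^2 & 0 \le t \le T_k \\
\lambda_k^{\max} & t > T_k,\end{cases}$$

a convex, accelerating toll that saturates once a victim has, in effect,
waited too long to be helped.  Demand that is never met is charged exactly
this plateau — an infinite wait — so unfairness and slowness are priced on
the same monetary scale.  For area $j$ and PPE $k$ the loss is

$$L_{jk} = \Big(d_{jk} - \sum_{h,i,m} y_{hijkm}\Big)\lambda_k^{\max}
  + \sum_{h,i,m} y_{hijkm}\,\lambda_k(e_m D_{hij}),$$

where $y$ is kilograms shipped along reserve$\to$DC$\to$area paths, $e_m$
the per-meter travel time of vehicle class $m$ and $D_{hij}$ the path
length.  The two objectives are

$$G_1 = \sum_{j,k} w_k L_{jk}, \qquad
  G_2 = \sum_i c_i z_i + \sum_{h,i,j,m} D_{hij} f_m x_{hijm},$$

with $w_k$ the PPE importance weights, $z_i$ binary DC openings, $x_{hijm}$
integer vehicle counts, $c_i$ rents and $f_m$ per-meter transport costs.
Constraints cap vehicles per reserve, stock per reserve, DC vehicle and
stock throughput (both gated by $z_i$), load per vehicle, delivery per
demand, and forbid paths beyond the coverage radius.

Because route times depend only on the fixed distance matrix, every
$\lambda_k(e_m D_{hij})$ is a constant and $G_1$ is *linear* in $y$.  The
whole problem is a mixed-integer linear program; `build_formulation()`
emits it with the coverage rule applied as variable-bound fixing (an upper
bound of zero on out-of-range $x$) rather than big-M rows, which keeps the
relaxation tight, and with $x_{hijm} \le \min(U_{hm}, P_{im})$ so the
search tree is finite.

## Goal programming and the solver

Humanitarian practice treats the loss objective as preemptively more
important than logistics cost.  `goal_spec()` fixes ideal levels $R_1, R_2$
(by default the single-objective optima computed by `ideal_levels()`) and
deviation variables $\theta_n^\pm \ge 0$ with rows
$G_n + \theta_n^- - \theta_n^+ = R_n$.  Two design points deserve note:

* **Complementarity** ($\theta_n^-\theta_n^+ = 0$) is a nonlinear condition
  and is *not* imposed as a constraint.  With both deviations non-negative,
  tied in one equality, and only $\theta^+$ penalized, an optimal basic
  solution never needs both positive; the solver verifies the product
  post hoc (`complementarity_ok`) instead of sacrificing linearity.
* **Preemption** is operationalized lexicographically: stage 1 minimizes
  $\theta_1^+$; stage 2 freezes it (up to a slack of
  $10^{-6}\max(1, |R_1|)$ — proportional to the ideal level because the
  loss objective is measured in units of $10^8$-plus yuan, where an
  absolute $10^{-6}$ would be below the solver's numerical resolution) and
  minimizes $\theta_2^+$.  A weighted single-objective mode
  (`priorities = c(1e6, 1)` by default, with a guarded minimum ratio) is
  provided for comparison.  Reported deviations are the complementary
  pair implied by the achieved objective values; the raw LP values are
  kept in `theta_raw`.

The mixed-integer programs are solved by LP-relaxation branch and bound
(`branch_and_bound()`): best-bound node selection, branching on the most
fractional integer variable with lowest-index tie-breaks, floor/ceiling
children, and pruning against the incumbent — all deterministic, so
identical inputs reproduce identical trees.  `improved_solve()` wraps it in
a warm-start procedure: solve the root relaxation and save its solution
and basis; fix DC-opening variables whose relaxation values fall below
`fix_zero = 0.01` (their routed and allocated flows are then near zero
too) to 0 and those above `fix_one = 0.9` to 1; solve that restricted
problem; then restore all bounds and re-solve the original program using
the restricted optimum as a cutoff.  The thresholds quantify a rule stated
only qualitatively ("close to 0", "relatively large"); because the
heuristic contributes nothing but a cutoff, the final solve still proves
optimality, and the package asserts improved $=$ plain on every test
instance.  The LP subroutine contract is deterministic-optimal; the saved
basis degrades gracefully to a cold start, which the in-package simplex
takes.

### The LP subroutine

No linear-programming backend is assumed; the package carries a dense
two-phase tableau simplex (`lp_solve()`) sized for this model family (a
few hundred rows and columns).  Numerical choices that matter:

* rows, then columns, then rows are equilibrated to unit magnitude, so one
  set of tolerances serves binary, vehicle-count and kilogram scales
  (raw coefficients span $10^{-2}$ to $10^4$ and right-hand sides reach
  $10^{10}$ via the goal rows);
* pivot eligibility requires tableau entries above $10^{-7}$; among
  near-minimal ratio-test rows the largest pivot element wins (stability),
  then the lowest basic index (determinism);
* Dantzig pricing switches to Bland's anti-cycling rule in place after 60
  consecutive degenerate pivots and switches back once the objective
  moves, so degenerate goal-stage LPs terminate without the cost of
  running Bland throughout;
* phase-1 feasibility is judged relative to the largest scaled right-hand
  side, and lower bounds are shifted out while finite upper bounds become
  explicit rows.

`boot::simplex` — an independent implementation — serves as a
cross-checking oracle in the test suite on hundreds of random small LPs;
it is never used in the solution path.

### Ground-truth oracles

`enumerate_oracle()` exhaustively enumerates DC openings and integer
vehicle assignments (refusing more than a configurable number of
combinations) and optimizes the continuous shipments by LP for each,
yielding the exact optimum of small instances; `oracle_goal()` does the
same two-stage search for the goal program.  The acceptance suite requires
plain branch and bound, the warm-started solver and the oracle to agree to
$10^{-6}$ relative on twenty seeded random instances per objective.

## Evaluation machinery

`ideal_levels()` and `worst_values()` bracket each objective.  The worst
loss has the closed form $\sum_{j,k} d_{jk}\lambda_k^{\max} w_k$ — no plan
can lose more than delivering nothing, since delivered kilograms are
charged at most the plateau — and the package cross-checks it by solving
the maximization MILP.  The worst cost is found by maximization only.
`percentage_deviation()` normalizes an achieved value between those
bounds; it is invariant under positive rescaling, errors on inverted
bounds, and returns 0 with a warning on degenerate ones.
`pareto_trace()` re-solves the goal program with the loss ideal inflated
by a multiplier grid, tracing the fairness-efficiency frontier (minimum
cost is provably non-increasing in the multiplier, and the suite asserts
it).  `sensitivity_scan()` repeats the solve across the grid and reports
the relative error of the warm-started solver against plain branch and
bound or the enumeration oracle; runtimes are recorded as information
only, never asserted, because they are hardware-dependent.

## The packaged case and the synthetic generator

`wenzhou_case()` carries the published case tables: five affected areas
with mask demand 931 t and protective-clothing demand 14.6 t (clothing
supply, 12 t, is deliberately short — the shortage regime the loss
function exists for), three reserve centers, two candidate DCs with rents
of 800,000 and 600,000 yuan, three vehicle classes, importance weights
0.6/0.4, a 150 km coverage radius, and the waiting-cost curve
$t^2/7315661$ capped at 50,000 yuan/kg past one week (604,800 s).  Stock
tables are declared in thousands of kilograms and converted to kilograms
on load; kilograms, meters, seconds and yuan are the canonical units
everywhere.  One curve is shared by both PPE types, as in the case; the
constructor accepts per-type curves for generality.

The case's reserve-DC-area distance matrix was never published.  The
package therefore *never* pretends to it: `wenzhou_case()` demands either
a user matrix or a seed, under which `synthetic_distances()` scatters the
sites on a 100 km planar region, applies a road factor of 1.3 to the two
Euclidean legs, and redraws until every area is reachable within coverage.
Quantities that depend on distances (the loss ideal $R_1$, the achieved
cost compromise, concrete routes) are consequently reproducible only per
seed; quantities derived from the tables alone — the worst-case loss
2.8222e10 yuan, the zero ideal of the cost objective, the curve values —
are exact regardless.

`synthetic_instance()` generalizes this into a seeded generator:
uniform site placement, road-factored distances, demands uniform in a
configurable range, per-PPE supplies scaled so that total supply equals
`rho` times total demand exactly (the default `rho = 0.8` keeps instances
in the shortage regime), fleet sizes, DC capacities drawn between 50% and
150% of the corresponding system totals so they sometimes bind, and
cost/time/capacity ranges bracketing the case magnitudes.  What it does
*not* emulate: real road networks (distances are inflated Euclidean sums),
correlated demand surges, multi-period dynamics, or stochastic supply
disruption.  Tests passing on these instances therefore certify the
optimization machinery, not any epidemiological realism of the inputs.

## Problem sizes and test design

The enumeration oracle anchors correctness on instances with two
reserves, two DCs, two areas, one PPE type, one vehicle class and fleets
of one or two vehicles — a few thousand (z, x) combinations each, solved
exhaustively.  The suite runs twenty such seeds through both solvers and
the oracle, linearization checks on two-PPE/two-vehicle instances, and
the full case instance for the table-derived quantities and the
zero-cost ideal; the complete suite runs in well under a minute.  These
sizes were chosen so the oracle remains exact (its purpose), not because
the solver is limited to them: the full case (2 binary, 90 integer, 180
continuous variables, 125 rows) solves its two-stage goal program in a
few seconds.

## Known limitations

* The solver is a pure-R dense simplex plus branch and bound; it is meant
  for case-study-scale networks (hundreds of variables), not for
  province-scale instances with thousands of paths.
* Vehicles traverse one reserve-DC-area path each, once; there is no
  routing within layers, no vehicle reuse, and no round-trip accounting.
* The waiting-cost family is fixed to quadratic-then-plateau.  The curve
  object validates continuity at the breakpoint to 1e-4 relative and the
  evaluator caps the quadratic branch at the plateau, so a curve within
  that tolerance never exceeds its declared maximum.
* Demand, supply and travel times are deterministic; scenario or
  multi-period extensions are out of scope.
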