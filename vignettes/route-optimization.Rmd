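---
title: "Route optimization for last-mile vaccine distribution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Route optimization for last-mile vaccine distribution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lastmile)
```

## The problem

A district medical store (the *depot*) must deliver a month's vaccines and
medical supplies to a set of health centers using a small, heterogeneous
fleet. Vaccines ride in passive cold boxes, so each vehicle has a separate
*cold* and *dry* compartment volume, and every route must finish within a
maximum duration `l` (typically a working day, and bounded in practice by
cold-box holding time). Roads may be one-way, and both roads and vehicles
carry categorical condition labels: a rough road or an unreliable vehicle
raises the risk of breakage and temperature excursions, which the model
penalizes rather than forbids. The planner balances two goals - total
transit time and total condition penalties - with a single weight entered on
a 0..10 scale (`W_t = raw/10`, `W_p = 1 - W_t`).

`lastmile` implements this planning problem twice, deliberately:

* an exact mixed-integer program (MIP) over arc indicators, compartment
  flows and departure times, solved through an external open-source
  branch-and-cut backend; and
* a fast two-stage *index rule* construction heuristic embedded in an
  elite-set branch-and-bound with minimum-spanning-tree (MST) lower bounds,
  which returns a good feasible plan within a couple of minutes even when
  the exact model cannot be solved to optimality.

## Data model and preprocessing

An instance is seven tables (parameters, products, center capacities,
demand, vehicles, distance matrix, road conditions); see `read_instance()`.
Units are liters, kilometers and hours throughout. Transit times are derived
as `h[i,j,v] = distance[i,j] / velocity[v]` from the vehicle's average
velocity - the only speed information the input carries.

Three preprocessing steps run before any solver:

* **Weight normalization** (`normalize_weights()`): the 0..10 input becomes
  `(W_t, W_p)` with `W_t + W_p = 1`. Entering 10 optimizes transit time
  only; 0 optimizes penalties only.
* **Demand scaling** (`scale_demand()`): when a product's total demand
  exceeds the supply available at the depot, all centers are scaled back
  proportionally. We round to whole doses with largest-remainder
  redistribution (ties broken by center order) so column sums never exceed
  supply; whether to round at all is this package's choice, isolated in one
  function. A note recommends a repeat delivery when stock arrives.
* **Cold/dry grouping** (`group_products()`): the product dimension
  collapses to two classes, cold and dry, via per-center demand volumes
  `D_i^r` and `D_i^d` (liters). This is what keeps the exact model small -
  its variable count is `3|C|^2|V| + |C||V|` regardless of the catalogue -
  and the per-product detail is restored after solving
  (`disaggregate_products()`).

Storage-capacity overruns at a center are *warnings*, never errors: the
working assumption is that storage will be available when the delivery
arrives. Structural defects (no depot, dimension mismatches, nonpositive
velocity) are errors and block solving (`validate_instance()`).

Scaling means put heterogeneous quantities on one scale inside the
objective and the indices: `mu_h` (with its defining factor 2, which we keep
exactly as defined although a plain mean would look more natural; a
`double_mean` flag can disable it), `mu_gamma` over all `|C|^2` road
entries, `mu_beta` over vehicles, and `mu_cr`, `mu_cd`, `mu_v` over the
fleet. Arcs labeled "not accessible" carry an internal penalty value of 10
(continuing the monotone 1..8 scale) *only* for the purpose of this mean;
routing never uses such arcs because their availability is 0.

### Condition penalty scales

Users pick labels, not numbers. The numeric scales are configuration with
monotone defaults - roads: fully paved 1, partially paved 2, dirt (good) 3,
dirt (rough) 5, boat 6, foot 8, not accessible excluded via availability;
vehicles: very reliable 1 to unreliable 4 - and can be overridden, but the
published experiments used uniform penalties, so reported objective values
are insensitive to the exact choice there.

## The objective and its two forms

The cost of driving arc `(i,j)` with vehicle `v` is

```
W_t * exp(-h[i,j,v]/mu_h) + W_p * (exp(-gamma[i,j]/mu_gamma) + exp(-beta[v]/mu_beta))
```

summed over chosen arcs and minimized. This *printed* form is the model's
definition and reproduces the published objective magnitudes, but note its
direction: the exponentials *decrease* in time and penalty, so minimizing
them favors long, risky arcs - the opposite of the stated goals, and the
opposite of the construction index below, which is maximized. The package
therefore implements both this form (default) and an *increasing* form with
positive exponents whose minimization genuinely prefers short, safe arcs.
The discrepancy is documented rather than resolved; every solver, the
enumeration oracle in the tests, and the bounds respect whichever form is
active, so the cross-checks hold under both.

## The exact model

Variables: binary arc indicators `y[i,j,v]` (all pairs, diagonal fixed to
zero), continuous class flows `x[i,j,v,p]` in liters, and departure times
`t[i,v]` in hours. Constraint families: net flow into each center equals its
demand volume; the load leaving the depot fits each compartment; big-M time
sequencing (`t_j >= t_i + h + W` on used arcs, `W` the drop-off time);
return-to-depot within `l`; arcs/flows only for vehicles that depart the
depot; degree balance at every center; arcs restricted to available roads;
flow only on chosen arcs. Big-M values are `M_time = l + W + max h`,
`M_count = |C|^2` and `M_flow,p = ` total class volume; tests verify that
inflating them tenfold never moves the optimum.

Four readings were needed where the printed formulation is loose, and we
fixed them as follows:

* the demand-balance equality is applied for `j != depot`; at the depot it
  would contradict its role as the source;
* the depot-departure linking constraints have a free index as printed; we
  implement "a vehicle (or flow) is used only if it leaves the depot" as a
  sum over its arcs bounded by `M` times its depot departures;
* one route per vehicle is made explicit (`sum_j y[o,j,v] <= 1`): the model
  otherwise admits two disjoint depot loops sharing one set of time
  variables. Multiple routes per vehicle are the heuristic's extension and
  deliberately not part of the exact model;
* split deliveries (one center's volume on two vehicles) remain possible
  through the flows, and route extraction attributes each center's volume to
  the vehicle that carried it.

The backend is the HiGHS branch-and-cut solver, reached through
`scipy.optimize.milp` in a Python subprocess (models are serialized as
sparse triplets to JSON). Solutions report status, incumbent, dual bound and
gap; route extraction follows the chosen arcs from the depot and rejects any
leftover cycle as an integrity error. The model's time variables carry big-M
slack and only fix the visit order, so reports show the tight schedule
(cumulative driving plus drop-off), which is what the sequencing constraints
express at equality.

## The construction heuristic

Construction is two-staged and entirely deterministic:

1. **Vehicle choice** (`vehicle_index()`): vehicles are ranked by
   `exp(-beta/mu_beta) + exp(c_r/mu_cr) + exp(c_d/mu_cd) + exp(v/mu_v)` -
   reliable, large, fast vehicles first.
2. **Route growth** (`node_index()`): from the current center `i`, the next
   center is the feasible unserved `j` maximizing
   `W_t exp(-h[i,j,v]/mu_h) + W_p exp(-gamma[i,j]/mu_gamma)`.

A candidate is *feasible* (`feasible_extension()`) when the arc to it is
available, its cold and dry volumes fit the remaining compartments, and
after the drop-off the vehicle can still reach the depot within `l` - over
an available return arc, a condition we added beyond the obvious three
because availability applies to the closing arc too and the route could
otherwise never close legally. Ties in both indices break by input order
(vehicles, then centers), which makes every run reproducible.

When no candidate fits, the route closes and the next vehicle starts; after
every vehicle has one route the order restarts (*all vehicles before any
reuse*). The audit operationalizes that rule as: no vehicle may be two or
more routes ahead of another. Construction fails - naming the centers - only
when no vehicle can start a route to any remaining center.

## Elite-set branch-and-bound

The search tree branches on the first center of the top-ranked vehicle's
route, one initial branch per feasible first center. Because arc costs
depend on the vehicle (velocity and `beta`), we add one extra initial branch
that defers the top vehicle entirely; without it, plans that leave the best-
indexed vehicle idle would be unreachable and the search could not match the
exhaustive optimum. Each branch is completed greedily to an incumbent (the
*depth evaluation*), and an elite set of 12% of the branches (ceiling, at
least one per half once there are two branches) is selected: half by best
incumbent, half by largest *uncertainty* (incumbent minus the branch's local
lower bound), ties by branch creation order.

Branches are explored depth-first, children in decreasing node index, elite
branches first, round-robin with a quantum of 1000 node expansions so no
branch starves the rest; remaining branches follow if budget remains, so an
uncapped run (`budget_s = Inf`) is exact over the heuristic's solution
space. Within the search, a vehicle may also be left unused by free choice
only in the first round of the vehicle cycle, and a second round never opens
after a free skip - otherwise the all-before-reuse rule would be violated.

Pruning uses `committed cost + mst_lower_bound(unserved + endpoint + depot)
>= incumbent`. The MST bound is valid because every feasible completion's
arc set spans those nodes and all arc costs are positive; edge costs are the
cheapest available connection (minimum over vehicles and both directions of
the active-form arc cost). The reported global bound is the minimum local
bound over open nodes, floored by the root MST bound, and equals the
incumbent when the tree is exhausted - so the gap reaches zero at
convergence. The greedy solution initializes the incumbent, giving the
anytime guarantee that the search never returns anything worse.

The published lower bounds for the large districts cannot be reconstructed
from the MST description alone; bounds here are validated by their defining
property (never above the optimum on exhaustively solvable instances), not
against published bound values.

## Costs and reports

Fuel and per-diem costs are computed after optimization and never influence
it: fuel is distance times consumption times price; one per diem is charged
per executed route (a route fits within one working day by construction;
whether the allowance is per person or per vehicle-day is not specified in
the source material, so per vehicle-route-day is this package's documented
choice). Utilization denominators are the vehicle's capacities at route
start. The output is a `routes` table (summary row plus per-leg rows with
road condition and clock departure times) and a `products` table (per route
and center, doses per product), written as a CSV pair named
`<stem>_result_<date>_*.csv` with a numeric suffix on collision.

## The synthetic generator

`generate_instance()` emulates the published district shapes: 8-50 centers
with one depot, 1-6 vehicles with cold/dry compartments and condition
classes, 12-13 products split cold/dry, asymmetric distances (Euclidean base
times a directional jitter of +-10%), integer monthly demands, and
capacities tied to total demand volume through a tightness factor (above 1
provably forces more than one route, exercising vehicle reuse). Defaults -
a 120 km field, 40-70 km/h velocities, an 8 h route limit, 0.25 h drop-off,
equal objective weights, supply at 1.2x demand - were chosen once as
plausible district conditions. "Not accessible" roads are not drawn by
default: a connected road network is what a functioning district looks like,
and blanket random inaccessibility mostly produces depots that cannot reach
their own centers; inaccessible arcs are fully supported as explicit data.

What the generator does *not* emulate: real road topology (distances are
jittered Euclidean, so near-triangle-inequality holds), correlated or
seasonal demand, stockout patterns, and the actual penalty calibration of
any real district. Tests passing on synthetic instances therefore establish
the algorithms' correctness and internal consistency, not predictive claims
about any specific district.

## Numerical choices and test scale

* Feasibility and optimality tolerances are 1e-6; bound validity is asserted
  at 1e-9; means agree with re-summation at 1e-12.
* Degenerate zero means (e.g., an all-zero-capacity fleet) are treated as
  "at the mean" inside exponentials to keep indices finite.
* The exhaustive cross-check suite uses 50 instances with up to 6 centers
  and 2 vehicles - the largest family where full enumeration of assignments
  and visit orders is instant - and checks the exact model, the uncapped
  branch-and-bound and the enumerator against each other under both
  objective forms. The scale check runs the construction on a 50-center,
  5-vehicle district, where it completes in well under a second.
* Published variable counts for the six district shapes are reproduced
  exactly; published *constraint* counts cannot be reconciled with any
  counting of the printed constraint families and are reported
  (`n_constraints`) but not asserted.

## Known limitations

Multi-day routes, mixed transport modes, map-API distances, and inventory
policy are out of scope. The heuristic requires every center to be reachable
as a route endpoint (available depot return); a center reachable only
mid-route through one-way arcs can defeat the greedy even when the exact
model finds a plan. The direction question of the printed objective form
remains open, as discussed above. The exact model tolerates split
deliveries; the heuristic always serves a center in full from one vehicle.
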