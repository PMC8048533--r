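# lastmile

Route planning for last-mile distribution of vaccines and medical supplies:
a district store (depot) delivers a month's products to its health centers
with a small fleet whose vehicles have separate **cold** (refrigerated) and
**dry** compartments, over roads that may be one-way and in poor condition,
within a maximum route duration. It is written for health-logistics analysts
and planners who need a defensible delivery plan in minutes, plus the costs
that go with it.

## The model

Given centers `C` with depot `o`, vehicles `V`, per-center cold/dry demand
volumes (products are grouped into the two storage classes before
optimization and disaggregated afterwards), transit times
`h[i,j,v] = d[i,j]/velocity[v]`, road penalties `gamma[i,j]` and vehicle
penalties `beta[v]` derived from categorical condition labels, routes are
chosen to minimize the weighted arc cost

    W_t * exp(-h[i,j,v]/mu_h) + W_p * (exp(-gamma[i,j]/mu_gamma) + exp(-beta[v]/mu_beta))

summed over chosen arcs, subject to demand coverage, compartment capacities,
big-M time sequencing with a fixed drop-off time `W`, guaranteed return to
the depot within the duration limit `l`, and road availability. The means
`mu_*` put times and penalties on a common scale; `W_t + W_p = 1` comes from
a single 0..10 user weight. An `increasing` objective variant (positive
exponents) is also provided; see the methods vignette
(`vignettes/route-optimization.Rmd`) for why both forms exist.

Two solvers share this objective:

* **`solve_mip()`** - the exact mixed-integer program (binary arc
  indicators, class flows, departure times), solved by the open-source
  HiGHS branch-and-cut solver through a small Python/scipy backend;
* **`branch_and_bound()`** - a two-stage index heuristic (rank vehicles by
  `vehicle_index()`, grow routes by `node_index()` over feasible unserved
  centers, all vehicles used before any is reused) embedded in an elite-set
  branch-and-bound: every initial branch is greedily completed, the best 12%
  of branches (half by incumbent, half by uncertainty) are explored first,
  and nodes are pruned with minimum-spanning-tree lower bounds. Uncapped, it
  is exact over the heuristic's solution space; under a time budget it is
  anytime and never worse than `construct_greedy()`.

Fuel and per-diem costs are computed after optimization (`route_costs()`)
and reported, never optimized.

## Worked example

The packaged four-center fixture (depot `o`, centers `a`, `b`, `c`, one
very reliable vehicle) walks through the whole pipeline:

```r
library(lastmile)

inst <- fixture_four_centers()
g    <- group_products(inst)       # demand scaling + cold/dry grouping
sol  <- branch_and_bound(g, budget_s = 10)
sol
#> bnb solution (printed objective): 1 route(s), objective 2.50327, bound 2.50327, gap 0
#>   route 1 [4x4]: o -> a -> c -> b -> o (2.47 h)
```

The search proved optimality (gap 0): the route `o -> a -> c -> b -> o`
takes 2.47 h including three 15-minute drop-offs, well inside the 8 h limit.
The greedy construction alone gives 2.53094; the exact solver
(`solve_mip(build_mip(g))`) confirms 2.503272. Costs and the delivery
detail:

```r
route_costs(sol$routes[[1]], inst)
#> $distance_km   103
#> $fuel_cost     18.54
#> $per_diem_cost 500

departure_clock_times(sol$routes[[1]], "08:00")
#> "08:00" "08:45" "09:35" "10:06" "10:28"

disaggregate_products(sol, g)
#>   route center        product quantity volume_l
#>       1      a        measles      100      2.0
#>       1      a syringes 0.5ml      120      1.2
#>       1      b        measles      150      3.0
#>       1      b syringes 0.5ml      180      1.8
#>       1      c        measles       80      1.6
#>       1      c syringes 0.5ml       90      0.9
```

`write_solution(sol, g, dir, stem = "fixture")` writes the `routes` and
`products` report tables as `fixture_result_<date>_*.csv`. The same pipeline
runs from a shell via the script in `inst/cli/`:

```sh
Rscript inst/cli/lastmile generate -o district --centers 8 --vehicles 2 --seed 7
Rscript inst/cli/lastmile solve    -i district --solver bnb --budget 120
```

Instances live in a directory of seven CSV tables (parameters, products,
center_capacities, demand, vehicle, distance_data, road_condition); see
`?read_instance`.

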