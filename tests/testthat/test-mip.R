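test_that("arc costs follow the weighted exponential form", {
  # symmetric two-center instance: every quantity sits exactly at its mean
  inst <- two_center_instance()
  g <- group_products(inst)
  cost <- arc_cost_matrix(g, "V1")
  expect_equal(cost["o", "a"], 1.5 * exp(-1), tolerance = 1e-12)

  # weight boundary: only transit time counts
  inst10 <- two_center_instance(transit_weight = 10)
  g10 <- group_products(inst10)
  expect_equal(arc_cost_matrix(g10, "V1")["o", "a"], exp(-1), tolerance = 1e-12)

  # arbitrary values against an independent evaluation, both forms
  for (s in 1:4) {
    instr <- generate_instance(generator_spec(n_centers = 5, n_vehicles = 2,
                                              seed = 200 + s))
    gr <- group_products(instr)
    om <- oracle_means(instr)
    for (form in c("printed", "increasing")) {
      got <- arc_cost_matrix(gr, 2, form)
      h <- transit_matrix(instr, 2)
      want <- oracle_arc_cost(h["HC-01", "HC-02"],
                              instr$roads$gamma["HC-01", "HC-02"],
                              instr$vehicles$penalty[2],
                              gr$W_t, gr$W_p, om, form)
      expect_equal(got["HC-01", "HC-02"], want, tolerance = 1e-12)
    }
  }
})

test_that("the grouped model's variable count is 3|C|^2|V| + |C||V|", {
  g1 <- group_products(generate_instance(generator_spec(n_centers = 8,
                                                        n_vehicles = 1, seed = 1)))
  expect_identical(build_mip(g1)$n_variables, 200L)
  g2 <- group_products(generate_instance(generator_spec(n_centers = 13,
                                                        n_vehicles = 6, seed = 1)))
  expect_identical(build_mip(g2)$n_variables, 3120L)
})

test_that("a zero-demand model solves to an empty optimal routing", {
  inst <- generate_instance(generator_spec(n_centers = 4, n_vehicles = 1,
                                           demand_range = c(0, 0), seed = 2))
  g <- group_products(inst)
  ms <- solve_mip(build_mip(g))
  expect_identical(ms$status, "optimal")
  expect_equal(ms$objective, 0)
  expect_true(all(ms$y == 0))
  sol <- extract_routes(ms, g)
  expect_length(sol$routes, 0)
})

test_that("the exact model matches exhaustive enumeration on the fixture", {
  g <- group_products(fixture_four_centers())
  for (form in c("printed", "increasing")) {
    ms <- solve_mip(build_mip(g, objective_form = form))
    expect_identical(ms$status, "optimal")
    expect_equal(ms$objective, brute_force_optimum(g, form), tolerance = 1e-6)
    sol <- extract_routes(ms, g)
    expect_true(audit_solution(sol, g)$ok)
    # flow conservation: delivered volumes equal the grouped demand
    dl <- sol$deliveries
    expect_equal(sum(dl$cold_volume), sum(g$cold_demand), tolerance = 1e-6)
    expect_equal(sum(dl$dry_volume), sum(g$dry_demand), tolerance = 1e-6)
  }
})

test_that("route extraction orders arcs from the depot with increasing times", {
  g <- group_products(fixture_four_centers())
  sol <- extract_routes(solve_mip(build_mip(g)), g)
  expect_length(sol$routes, 1)
  rt <- sol$routes[[1]]
  expect_identical(rt$sequence[1], "o")
  expect_identical(rt$sequence[length(rt$sequence)], "o")
  expect_setequal(rt$sequence[-c(1, length(rt$sequence))], c("a", "b", "c"))
  expect_true(all(diff(rt$depart) > 0))
})

test_that("an unreachable demand center makes the model infeasible, with diagnosis", {
  inst <- fixture_four_centers()
  cond <- inst$roads$condition
  cond["o", "c"] <- cond["a", "c"] <- cond["b", "c"] <- "not accessible"
  inst2 <- instance(inst$centers, inst$products,
                    inst$vehicles[, setdiff(names(inst$vehicles), "penalty")],
                    inst$roads$distance, cond, inst$demand, inst$parameters)
  g <- group_products(inst2)
  ms <- solve_mip(build_mip(g))
  expect_identical(ms$status, "infeasible")
  expect_match(ms$diagnostic, "availability")
  expect_match(ms$diagnostic, "c")
})

test_that("the optimum is invariant to center input order", {
  inst <- generate_instance(oracle_suite_spec(31, 5, 2))
  g <- group_products(inst)
  obj1 <- solve_mip(build_mip(g))$objective
  inst_p <- permute_centers(inst, c(3, 1, 5, 2, 4))
  obj2 <- solve_mip(build_mip(group_products(inst_p)))$objective
  expect_equal(obj1, obj2, tolerance = 1e-7)
})

test_that("growing the big-M constants does not move the optimum", {
  for (s in c(8, 21)) {
    g <- group_products(generate_instance(oracle_suite_spec(s, 5, 2)))
    base <- solve_mip(build_mip(g))$objective
    wide <- solve_mip(build_mip(g, big_M_scale = 10))$objective
    expect_equal(base, wide, tolerance = 1e-6)
  }
})
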