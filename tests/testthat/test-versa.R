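test_that("the vehicle index prefers reliable, large, fast vehicles", {
  # all attributes at the fleet means: e^-1 + 3e
  inst <- two_center_instance()
  m <- compute_means(inst)
  expect_equal(vehicle_index(inst$vehicles[1, ], m), exp(-1) + 3 * exp(1),
               tolerance = 1e-12)

  # identical vehicles except reliability: lower penalty wins
  inst2 <- split_instance()
  inst2$vehicles$condition_class <- c("very reliable", "unreliable")
  inst2$vehicles$penalty <- map_vehicle_condition(inst2$vehicles$condition_class)
  m2 <- compute_means(inst2)
  expect_gt(vehicle_index(inst2$vehicles[1, ], m2),
            vehicle_index(inst2$vehicles[2, ], m2))

  # arbitrary vehicle against a direct evaluation
  inst3 <- generate_instance(generator_spec(n_centers = 5, n_vehicles = 3,
                                            seed = 17))
  m3 <- compute_means(inst3)
  v <- inst3$vehicles[2, ]
  expect_equal(vehicle_index(v, m3),
               exp(-v$penalty / m3$mu_beta) + exp(v$cold_capacity / m3$mu_cr) +
                 exp(v$dry_capacity / m3$mu_cd) + exp(v$velocity / m3$mu_v),
               tolerance = 1e-12)
})

test_that("the node index prefers near centers on good roads", {
  # h and gamma at their means with equal weights: e^-1
  g <- group_products(two_center_instance())
  expect_equal(node_index(g, "o", "a", "V1"), exp(-1), tolerance = 1e-12)

  # transit-only weight and a vanishing distance approach the supremum 1
  # (one short arc in a triangle: the transit mean stays away from zero)
  inst <- triangle_instance(d = 60)
  inst$roads$distance["o", "a"] <- inst$roads$distance["a", "o"] <- 0.001
  inst$parameters$transit_weight_raw <- 10
  w <- normalize_weights(10)
  inst$parameters$W_t <- w[["W_t"]]
  inst$parameters$W_p <- w[["W_p"]]
  g2 <- group_products(inst)
  expect_gt(node_index(g2, "o", "a", "V1"), 0.999)

  # four-center fixture: hand-evaluated scores drive the greedy chain
  gf <- group_products(fixture_four_centers())
  mf <- oracle_means(gf$instance)
  score <- function(i, j) {
    h <- gf$instance$roads$distance[i, j] / gf$instance$vehicles$velocity[1]
    0.5 * exp(-h / mf$mu_h) + 0.5 * exp(-gf$instance$roads$gamma[i, j] / mf$mu_gamma)
  }
  for (j in c("a", "b", "c"))
    expect_equal(node_index(gf, "o", j, 1), score("o", j), tolerance = 1e-12)
  first <- c("a", "b", "c")[which.max(sapply(c("a", "b", "c"), score, i = "o"))]
  expect_identical(first, "b")
  sol <- construct_greedy(gf)
  expect_identical(sol$routes[[1]]$sequence[2], "b")
})

test_that("extension feasibility checks availability, capacity and the return leg", {
  g <- group_products(fixture_four_centers())
  st <- route_state(g, "4x4")
  expect_true(feasible_extension(st, "b", g)$ok)

  blocked <- fixture_four_centers()
  cond <- blocked$roads$condition
  cond["o", "b"] <- "not accessible"
  blocked2 <- instance(blocked$centers, blocked$products,
                       blocked$vehicles[, setdiff(names(blocked$vehicles), "penalty")],
                       blocked$roads$distance, cond, blocked$demand,
                       blocked$parameters)
  gb <- group_products(blocked2)
  expect_identical(feasible_extension(route_state(gb, 1), "b", gb)$reason,
                   "availability")

  # return leg exactly exhausting the limit is accepted; a minute more is not
  exact <- two_center_instance(d = 60, velocity = 60, l = 2.25, W = 0.25)
  ge <- group_products(exact)
  expect_true(feasible_extension(route_state(ge, 1), "a", ge)$ok)
  tight <- two_center_instance(d = 60, velocity = 60, l = 2.25 - 1 / 60, W = 0.25)
  gt <- group_products(tight)
  res <- feasible_extension(route_state(gt, 1), "a", gt)
  expect_false(res$ok)
  expect_identical(res$reason, "time")

  # a center whose cold volume exceeds the remaining compartment is rejected
  heavy <- two_center_instance(demand_a = 10000)  # 100 L vs 50 L compartment
  gh <- group_products(heavy)
  expect_identical(feasible_extension(route_state(gh, 1), "a", gh)$reason,
                   "cold-capacity")
})

test_that("greedy construction follows the index chain and the reuse rule", {
  # ample single vehicle: one route through all three centers
  g <- group_products(fixture_four_centers())
  sol <- construct_greedy(g)
  expect_length(sol$routes, 1)
  expect_setequal(sol$routes[[1]]$sequence[-c(1, 5)], c("a", "b", "c"))
  expect_true(audit_solution(sol, g)$ok)
  # the chain is the argmax of the node index at every step (enumerated)
  expect_identical(sol$routes[[1]]$sequence, c("o", "b", "c", "a", "o"))

  # demand volume forcing a split: both vehicles run before any reuse
  gs <- group_products(split_instance())
  sols <- construct_greedy(gs)
  expect_gte(length(sols$routes), 2)
  expect_setequal(vapply(sols$routes[1:2], `[[`, character(1), "vehicle"),
                  c("V1", "V2"))
  expect_true(audit_solution(sols, gs)$ok)

  # zero demand: empty solution
  g0 <- group_products(generate_instance(generator_spec(
    n_centers = 4, n_vehicles = 1, demand_range = c(0, 0), seed = 1)))
  expect_length(construct_greedy(g0)$routes, 0)

  # unreachable center: infeasibility names it
  blocked <- fixture_four_centers()
  cond <- blocked$roads$condition
  cond[, "c"] <- "not accessible"
  gb <- group_products(instance(
    blocked$centers, blocked$products,
    blocked$vehicles[, setdiff(names(blocked$vehicles), "penalty")],
    blocked$roads$distance, cond, blocked$demand, blocked$parameters))
  expect_error(construct_greedy(gb), "c")
})

test_that("the MST bound is valid and tight in forced cases", {
  # equilateral triangle: the MST is any two edges, weight 2c
  g <- group_products(triangle_instance())
  c1 <- arc_cost_matrix(g, 1)["o", "a"]
  expect_equal(as.numeric(mst_lower_bound(g, c("o", "a", "b"))), 2 * c1,
               tolerance = 1e-12)

  # single unserved center: cheapest depot connection
  expect_equal(as.numeric(mst_lower_bound(g, c("o", "a"))), c1,
               tolerance = 1e-12)

  # agreement with an independent MST implementation on generated instances
  for (s in 1:5) {
    gi <- group_products(generate_instance(oracle_suite_spec(300 + s, 6, 2)))
    nodes <- seq_len(6)
    got <- as.numeric(mst_lower_bound(gi, nodes))
    m <- matrix(Inf, 6, 6)
    for (v in 1:2) {
      cv <- arc_cost_matrix(gi, v)
      cv[gi$instance$roads$availability != 1] <- Inf
      m <- pmin(m, cv, t(cv))
    }
    gr <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    want <- sum(igraph::E(igraph::mst(gr, weights = igraph::E(gr)$weight))$weight)
    expect_equal(got, want, tolerance = 1e-10)
  }

  # never above the exhaustive optimum
  for (s in 1:5) {
    gi <- group_products(generate_instance(oracle_suite_spec(400 + s, 5, 1)))
    targets <- which(gi$cold_demand + gi$dry_demand > 0)
    dep <- which(gi$instance$centers$is_depot)
    expect_lte(as.numeric(mst_lower_bound(gi, c(dep, targets))),
               brute_force_optimum(gi, "printed") + 1e-9)
  }
})

test_that("branch-and-bound is exact on small instances and anytime-safe", {
  # enumerated optimum reached with zero gap when uncapped
  for (s in 1:6) {
    gi <- group_products(generate_instance(oracle_suite_spec(500 + s,
                                                             4 + s %% 3,
                                                             1 + s %% 2)))
    bb <- branch_and_bound(gi, budget_s = Inf)
    expect_equal(bb$objective, brute_force_optimum(gi, "printed"),
                 tolerance = 1e-6)
    expect_lte(bb$bound, bb$objective + 1e-9)
    expect_equal(bb$gap, 0, tolerance = 1e-9)
    expect_true(audit_solution(bb, gi)$ok)
  }

  # a vanishing budget still returns at least the greedy solution
  gi <- group_products(generate_instance(generator_spec(n_centers = 9,
                                                        n_vehicles = 2,
                                                        field_km = 100,
                                                        max_route_hours = 10,
                                                        seed = 77)))
  greedy <- construct_greedy(gi)
  bb <- branch_and_bound(gi, budget_s = 1e-9)
  expect_lte(bb$objective, greedy$objective + 1e-12)
  expect_true(audit_solution(bb, gi)$ok)
})

test_that("the elite set takes 12% of branches, split best/uncertain", {
  # 11 centers, one ample vehicle: ten feasible first centers = ten branches
  # (the elite composition is fixed before exploration; a short budget is fine)
  gi <- group_products(generate_instance(oracle_suite_spec(9, 11, 1)))
  bb <- branch_and_bound(gi, budget_s = 2)
  expect_identical(bb$search$n_branches, 10L)
  expect_identical(bb$search$elite_size, 2L)
  expect_identical(bb$search$n_best, 1L)
  expect_identical(bb$search$n_uncertainty, 1L)
})

test_that("the search is deterministic", {
  gi <- group_products(generate_instance(generator_spec(n_centers = 8,
                                                        n_vehicles = 2,
                                                        seed = 13)))
  a <- branch_and_bound(gi, budget_s = Inf)
  b <- branch_and_bound(gi, budget_s = Inf)
  expect_identical(a$objective, b$objective)
  expect_identical(a$routes, b$routes)
})
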