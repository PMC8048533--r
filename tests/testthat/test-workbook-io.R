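test_that("condition labels map to monotone penalty scales", {
  r <- map_road_condition(ROAD_CONDITIONS)
  expect_true(all(diff(r$gamma) > 0))
  expect_equal(map_road_condition("fully paved")$gamma, 1)
  expect_true(map_road_condition("fully paved")$available)
  expect_false(map_road_condition("not accessible")$available)
  expect_error(map_road_condition("paved-ish"), "paved-ish")

  expect_equal(map_vehicle_condition(VEHICLE_CONDITIONS), 1:4)
  expect_equal(map_vehicle_condition("very reliable"), 1)
  expect_equal(map_vehicle_condition("unreliable"), 4)
  expect_error(map_vehicle_condition("rusty"), "rusty")
})

test_that("instances round-trip through the table directory format", {
  inst <- generate_instance(generator_spec(n_centers = 7, n_vehicles = 2,
                                           seed = 42))
  dir <- withr::local_tempdir()
  write_instance(inst, dir)
  back <- read_instance(dir)

  expect_equal(back$centers, inst$centers)
  expect_equal(back$products, inst$products)
  expect_equal(back$vehicles, inst$vehicles)
  expect_equal(back$demand, inst$demand)
  expect_equal(back$roads$distance, inst$roads$distance)
  expect_equal(back$roads$condition, inst$roads$condition)
  expect_equal(back$roads$gamma, inst$roads$gamma)
  expect_equal(back$parameters$W_t, inst$parameters$W_t)
  expect_equal(back$parameters$max_route_hours, inst$parameters$max_route_hours)

  # asymmetric entries survive (one-way roads are legitimate data)
  expect_false(isSymmetric(inst$roads$distance))
  expect_equal(back$roads$distance["HC-01", "HC-02"],
               inst$roads$distance["HC-01", "HC-02"])
})

test_that("reader names the missing table and rejects unknown labels", {
  inst <- generate_instance(generator_spec(n_centers = 5, seed = 7))
  dir <- withr::local_tempdir()
  write_instance(inst, dir)

  file.remove(file.path(dir, "vehicle.csv"))
  expect_error(read_instance(dir), "'vehicle'")

  write_instance(inst, dir)
  rc <- utils::read.csv(file.path(dir, "road_condition.csv"), check.names = FALSE)
  rc[2, 3] <- "paved-ish"
  utils::write.csv(rc, file.path(dir, "road_condition.csv"), row.names = FALSE)
  expect_error(read_instance(dir), "paved-ish")
})

test_that("solution reports round-trip and follow the result filename rule", {
  inst <- generate_instance(generator_spec(n_centers = 6, n_vehicles = 2,
                                           seed = 5))
  g <- group_products(inst)
  sol <- construct_greedy(g)
  dir <- withr::local_tempdir()
  paths <- write_solution(sol, g, dir, stem = "district", date = as.Date("2026-01-15"))
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths[1]), "^district_result_2026-01-15_routes\\.csv$")

  routes <- utils::read.csv(paths[1], check.names = FALSE)
  expect_equal(sum(routes$row_type == "summary"), length(sol$routes))
  expect_equal(unique(stats::na.omit(routes$run_description)),
               inst$parameters$run_description)
  products <- utils::read.csv(paths[2], check.names = FALSE)
  # per-product doses reconcile with the scaled demand of served centers
  served <- unique(sol$deliveries$center)
  expect_equal(sum(products$quantity),
               sum(g$scaled_demand[served, ]))

  # same stem on the same day gets a collision-avoiding suffix
  paths2 <- write_solution(sol, g, dir, stem = "district",
                           date = as.Date("2026-01-15"))
  expect_match(basename(paths2[1]), "district_result_2026-01-15-2_routes.csv",
               fixed = TRUE)
})

test_that("a zero-demand run writes a valid empty report", {
  inst <- generate_instance(generator_spec(n_centers = 4, n_vehicles = 1,
                                           demand_range = c(0, 0), seed = 3))
  g <- group_products(inst)
  sol <- construct_greedy(g)
  expect_identical(length(sol$routes), 0L)
  expect_identical(sol$objective, 0)
  dir <- withr::local_tempdir()
  paths <- write_solution(sol, g, dir)
  routes <- utils::read.csv(paths[1], check.names = FALSE)
  expect_identical(nrow(routes), 0L)
})
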