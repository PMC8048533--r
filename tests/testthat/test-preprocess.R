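test_that("the 0..10 weight input normalizes to complementary weights", {
  expect_equal(normalize_weights(10), c(W_t = 1, W_p = 0))
  expect_equal(normalize_weights(0), c(W_t = 0, W_p = 1))
  expect_equal(normalize_weights(6), c(W_t = 0.6, W_p = 0.4))
  expect_error(normalize_weights(11), "\\[0, 10\\]")
  expect_error(normalize_weights(-1), "\\[0, 10\\]")
})

test_that("demand is scaled back proportionally to the available supply", {
  prod <- data.frame(available_supply = 100)
  out <- scale_demand(matrix(c(60, 60), 2, 1), prod)
  expect_equal(as.numeric(out$demand), c(50, 50))
  expect_true(out$scaled)

  # ample supply: untouched
  prod2 <- data.frame(available_supply = 200)
  out2 <- scale_demand(matrix(c(60, 60), 2, 1), prod2)
  expect_equal(as.numeric(out2$demand), c(60, 60))
  expect_false(out2$scaled)

  # largest-remainder with ties broken by center order
  prod3 <- data.frame(available_supply = 2)
  out3 <- scale_demand(matrix(c(1, 1, 1), 3, 1), prod3)
  expect_equal(as.numeric(out3$demand), c(1, 1, 0))
})

test_that("scaling never increases demand and never exceeds supply", {
  set.seed(99)
  for (rep in 1:20) {
    d <- matrix(sample(0:50, 12, replace = TRUE), 4, 3)
    prod <- data.frame(available_supply = sample(10:120, 3))
    out <- scale_demand(d, prod)
    expect_true(all(out$demand <= d))
    expect_true(all(colSums(out$demand) <= prod$available_supply))
    expect_true(all(out$demand == floor(out$demand)))
  }
})

test_that("cold/dry grouping sums demand volumes per class", {
  # one cold product, 0.01 L/dose, 100 doses at one center
  inst <- two_center_instance(demand_a = 100)
  g <- group_products(inst)
  expect_equal(as.numeric(g$cold_demand), c(0, 1.0))
  expect_equal(as.numeric(g$dry_demand), c(0, 0))

  # all products dry: cold volumes vanish
  inst$products$requires_cold <- FALSE
  g2 <- group_products(inst)
  expect_true(all(g2$cold_demand == 0))
  expect_equal(as.numeric(g2$dry_demand), c(0, 1.0))
})

test_that("grouping conserves volume against a per-product re-summation", {
  for (s in 1:6) {
    inst <- generate_instance(generator_spec(n_centers = 6, n_products = 9,
                                             supply_factor = 0.8, seed = s))
    g <- group_products(inst)
    k <- inst$products$unit_volume
    cold <- as.logical(inst$products$requires_cold)
    for (i in seq_len(nrow(inst$centers))) {
      expect_equal(g$cold_demand[[i]],
                   sum(g$scaled_demand[i, cold] * k[cold]))
      expect_equal(g$dry_demand[[i]],
                   sum(g$scaled_demand[i, !cold] * k[!cold]))
    }
    expect_equal(sum(g$cold_demand) + sum(g$dry_demand),
                 sum(g$scaled_demand %*% k))
    # supply shortfall (factor 0.8) must have triggered a scaling note
    expect_gt(length(g$scaling_notes), 0)
  }
})

test_that("storage warnings count exceeded (center, class) pairs", {
  inst <- two_center_instance(demand_a = 120)  # 1.2 L cold at center a
  inst$centers$cold_capacity <- c(100, 1.0)
  g <- group_products(inst)
  expect_length(storage_warnings(g), 1L)

  inst$centers$cold_capacity <- c(100, 100)
  expect_length(storage_warnings(group_products(inst)), 0L)

  # both classes short at one center
  inst2 <- split_instance()
  inst2$products <- rbind(inst2$products, data.frame(
    name = "gloves", unit_volume = 0.05, doses_per_vial = 1L,
    requires_cold = FALSE, available_supply = 5000))
  inst2$demand <- cbind(inst2$demand, gloves = c(0, 40, 0, 0, 0))
  inst2$centers$cold_capacity <- 0.5
  inst2$centers$dry_capacity <- 0.5
  g2 <- group_products(instance(
    inst2$centers, inst2$products,
    inst2$vehicles[, setdiff(names(inst2$vehicles), "penalty")],
    inst2$roads$distance, inst2$roads$condition, inst2$demand,
    inst2$parameters))
  w <- storage_warnings(g2)
  expect_length(grep("at a ", w), 2L)
})
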