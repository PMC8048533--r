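# hand-sized instances for unit tests, fully specified so expected values can
# be computed on paper

# two centers, one vehicle: symmetric distance d, one road label everywhere.
# with the doubled transit mean, the off-diagonal h equals mu_h exactly, and
# a single label/vehicle puts gamma and beta at their means too.
two_center_instance <- function(d = 60, velocity = 60, label = "fully paved",
                                transit_weight = 5, l = 8, W = 0.25,
                                demand_a = 100) {
  cn <- c("o", "a")
  instance(
    centers = data.frame(name = cn, center_type = c("store", "hc"),
                         cold_capacity = c(100, 100), dry_capacity = c(100, 100),
                         is_depot = c(TRUE, FALSE)),
    products = data.frame(name = "vaccine", unit_volume = 0.01,
                          doses_per_vial = 10L, requires_cold = TRUE,
                          available_supply = max(1000, demand_a)),
    vehicles = data.frame(name = "V1", condition_class = "very reliable",
                          velocity = velocity, cold_capacity = 50,
                          dry_capacity = 50, fuel_consumption = 0.1,
                          fuel_price = 1.5, per_diem = 500),
    distance = matrix(c(0, d, d, 0), 2, 2, dimnames = list(cn, cn)),
    road_condition = matrix(label, 2, 2, dimnames = list(cn, cn)),
    demand = matrix(c(0, demand_a), 2, 1, dimnames = list(cn, "vaccine")),
    parameters = list(run_description = "two-center test",
                      start_location = "o", start_time = "08:00",
                      max_route_hours = l, dropoff_time = W,
                      transit_weight_raw = transit_weight))
}

# equilateral triangle: depot plus two centers, all distances equal
triangle_instance <- function(d = 30, label = "fully paved") {
  cn <- c("o", "a", "b")
  dm <- matrix(d, 3, 3, dimnames = list(cn, cn))
  diag(dm) <- 0
  instance(
    centers = data.frame(name = cn, center_type = "hc",
                         cold_capacity = 100, dry_capacity = 100,
                         is_depot = c(TRUE, FALSE, FALSE)),
    products = data.frame(name = "vaccine", unit_volume = 0.01,
                          doses_per_vial = 10L, requires_cold = TRUE,
                          available_supply = 1000),
    vehicles = data.frame(name = "V1", condition_class = "very reliable",
                          velocity = 60, cold_capacity = 50, dry_capacity = 50,
                          fuel_consumption = 0.1, fuel_price = 1.5,
                          per_diem = 500),
    distance = dm,
    road_condition = matrix(label, 3, 3, dimnames = list(cn, cn)),
    demand = matrix(c(0, 50, 50), 3, 1, dimnames = list(cn, "vaccine")),
    parameters = list(run_description = "triangle test", start_location = "o",
                      start_time = "08:00", max_route_hours = 8,
                      dropoff_time = 0.25, transit_weight_raw = 5))
}

# two identical vehicles and four centers whose combined demand volume does
# not fit in one vehicle, forcing at least two routes
split_instance <- function() {
  cn <- c("o", "a", "b", "c", "d")
  dm <- matrix(25, 5, 5, dimnames = list(cn, cn))
  diag(dm) <- 0
  veh <- data.frame(name = c("V1", "V2"),
                    condition_class = "reliable", velocity = 60,
                    cold_capacity = 2.5, dry_capacity = 50,
                    fuel_consumption = 0.1, fuel_price = 1.5, per_diem = 500)
  instance(
    centers = data.frame(name = cn, center_type = "hc", cold_capacity = 100,
                         dry_capacity = 100,
                         is_depot = c(TRUE, rep(FALSE, 4))),
    products = data.frame(name = "vaccine", unit_volume = 0.01,
                          doses_per_vial = 10L, requires_cold = TRUE,
                          available_supply = 5000),
    vehicles = veh,
    distance = dm,
    road_condition = matrix("fully paved", 5, 5, dimnames = list(cn, cn)),
    demand = matrix(c(0, 100, 100, 100, 100), 5, 1,
                    dimnames = list(cn, "vaccine")),
    parameters = list(run_description = "split test", start_location = "o",
                      start_time = "08:00", max_route_hours = 8,
                      dropoff_time = 0.25, transit_weight_raw = 5))
}

# permute the center order of an instance (depot flag travels with its row)
permute_centers <- function(inst, perm) {
  instance(
    centers = inst$centers[perm, ],
    products = inst$products,
    vehicles = inst$vehicles[, setdiff(names(inst$vehicles), "penalty")],
    distance = inst$roads$distance[perm, perm],
    road_condition = inst$roads$condition[perm, perm],
    demand = inst$demand[perm, , drop = FALSE],
    parameters = inst$parameters)
}
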