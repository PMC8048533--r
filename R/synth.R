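#' Specification for the synthetic district generator
#'
#' Describes a district-like instance family: centers placed uniformly in a
#' square field with near-Euclidean but asymmetric road distances,
#' categorical road conditions drawn from a label distribution, a product
#' catalogue split into cold and dry, integer monthly demands, and a fleet
#' whose compartment capacities are sized relative to the total demand volume
#' through a tightness factor (values above 1 force more than one route).
#' Defaults mirror a mid-sized district: 8 centers, 2 vehicles, 13 products
#' about half of which need refrigeration, an eight-hour route limit and a
#' quarter-hour drop-off, with the two objectives weighted equally.
#'
#' @param n_centers number of centers including the depot (>= 2).
#' @param n_vehicles fleet size.
#' @param n_products catalogue size.
#' @param frac_cold fraction of products needing refrigeration.
#' @param field_km side of the square placement field (km).
#' @param demand_range integer range of per-center per-product monthly demand
#'   (doses/units).
#' @param capacity_tightness total demand volume per class divided by total
#'   fleet capacity of that class; < 1 leaves slack, > 1 forces vehicle
#'   reuse over several routes.
#' @param supply_factor available supply as a multiple of total demand
#'   (< 1 forces demand scaling).
#' @param road_condition_probs named probabilities over [ROAD_CONDITIONS].
#' @param asymmetry relative directional jitter on distances.
#' @param max_route_hours,dropoff_time,transit_weight run parameters.
#' @param seed integer seed; the same spec always yields the same instance.
#' @return a list of class `lm_genspec`.
#' @export
generator_spec <- function(n_centers = 8, n_vehicles = 2, n_products = 13,
                           frac_cold = 0.5, field_km = 120,
                           demand_range = c(20, 400),
                           capacity_tightness = 0.6, supply_factor = 1.2,
                           road_condition_probs = c(
                             "fully paved" = 0.30, "partially paved" = 0.25,
                             "dirt road (good quality)" = 0.20,
                             "dirt road (rough quality)" = 0.15,
                             "boat access only" = 0.05,
                             "foot access only" = 0.05,
                             "not accessible" = 0),
                           asymmetry = 0.1, max_route_hours = 8,
                           dropoff_time = 0.25, transit_weight = 5,
                           seed = 1L) {
  if (n_centers < 2) stop("n_centers must be at least 2", call. = FALSE)
  if (n_vehicles < 1) stop("n_vehicles must be at least 1", call. = FALSE)
  if (n_products < 1) stop("n_products must be at least 1", call. = FALSE)
  stopifnot(setequal(names(road_condition_probs), ROAD_CONDITIONS),
            all(road_condition_probs >= 0),
            length(demand_range) == 2, demand_range[1] <= demand_range[2])
  structure(as.list(environment()), class = "lm_genspec")
}

.cold_names <- c("BCG", "OPV", "measles", "pentavalent", "PCV", "rotavirus",
                 "IPV", "tetanus toxoid", "HepB", "yellow fever",
                 "meningococcal", "typhoid", "HPV", "rabies", "cholera")
.dry_names <- c("syringes 0.5ml", "syringes 5ml", "safety boxes", "diluent",
                "cotton", "gloves", "paracetamol", "ORS sachets", "vitamin A",
                "bandages", "antimalarials", "zinc", "soap", "masks",
                "gauze")

#' Generate a synthetic district instance
#'
#' @param spec an `lm_genspec` from [generator_spec()].
#' @return an `lm_instance` that passes [validate_instance()] without errors.
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "lm_genspec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  nC <- spec$n_centers; nV <- spec$n_vehicles; nP <- spec$n_products
  cnames <- c("Depot", sprintf("HC-%02d", seq_len(nC - 1L)))

  xy <- matrix(stats::runif(2 * nC, 0, spec$field_km), ncol = 2)
  eu <- as.matrix(stats::dist(xy))
  jit <- matrix(stats::runif(nC * nC, -spec$asymmetry, spec$asymmetry), nC, nC)
  distance <- round(eu * (1 + jit), 3)
  diag(distance) <- 0

  cond <- matrix(sample(ROAD_CONDITIONS, nC * nC, replace = TRUE,
                        prob = spec$road_condition_probs), nC, nC)
  diag(cond) <- "fully paved"

  n_cold <- round(spec$frac_cold * nP)
  requires_cold <- sample(rep(c(TRUE, FALSE), c(n_cold, nP - n_cold)))
  pnames <- character(nP)
  pnames[requires_cold] <- rep_len(.cold_names, n_cold)
  pnames[!requires_cold] <- rep_len(.dry_names, nP - n_cold)
  products <- data.frame(
    name = pnames,
    unit_volume = round(stats::runif(nP, 0.002, 0.03), 4),
    doses_per_vial = sample(c(1L, 5L, 10L, 20L), nP, replace = TRUE),
    requires_cold = requires_cold,
    available_supply = 0)  # filled below from the drawn demand

  dvals <- seq(spec$demand_range[1], spec$demand_range[2])
  demand <- matrix(dvals[sample.int(length(dvals), nC * nP, replace = TRUE)],
                   nC, nP)
  demand[1, ] <- 0
  products$available_supply <- ceiling(colSums(demand) * spec$supply_factor)

  vol_cold <- as.numeric(demand[, requires_cold, drop = FALSE] %*%
                           products$unit_volume[requires_cold])
  vol_dry <- as.numeric(demand[, !requires_cold, drop = FALSE] %*%
                          products$unit_volume[!requires_cold])
  centers <- data.frame(
    name = cnames,
    center_type = c("district store",
                    sample(c("health center", "health post", "rural hospital"),
                           nC - 1L, replace = TRUE)),
    cold_capacity = round(pmax(vol_cold * 1.5, 5), 1),
    dry_capacity = round(pmax(vol_dry * 1.5, 10), 1),
    is_depot = c(TRUE, rep(FALSE, nC - 1L)))

  share_cold <- sum(vol_cold) / nV
  share_dry <- sum(vol_dry) / nV
  vehicles <- data.frame(
    name = sprintf("V%d", seq_len(nV)),
    condition_class = sample(VEHICLE_CONDITIONS, nV, replace = TRUE,
                             prob = c(0.4, 0.3, 0.2, 0.1)),
    velocity = round(stats::runif(nV, 40, 70)),
    cold_capacity = round(pmax(share_cold / spec$capacity_tightness *
                                 stats::runif(nV, 0.9, 1.1),
                               1.05 * max(vol_cold)), 1),
    dry_capacity = round(pmax(share_dry / spec$capacity_tightness *
                                stats::runif(nV, 0.9, 1.1),
                              1.05 * max(vol_dry)), 1),
    fuel_consumption = round(stats::runif(nV, 0.08, 0.2), 3),
    fuel_price = round(stats::runif(nV, 1.2, 1.8), 2),
    per_diem = sample(300:800, nV, replace = TRUE))

  parameters <- list(
    run_description = sprintf("synthetic district (seed %d)", spec$seed),
    start_location = "Depot", start_time = "08:00",
    max_route_hours = spec$max_route_hours,
    dropoff_time = spec$dropoff_time,
    transit_weight_raw = spec$transit_weight)

  instance(centers, products, vehicles, distance, cond, demand, parameters)
}

#' Four-center worked fixture
#'
#' A deliberately tiny, tie-free instance -- depot `o` plus centers `a`, `b`,
#' `c`, one very reliable vehicle (penalty 1) -- with hand-chosen distances
#' and road conditions, used to walk through the construction index: from the
#' depot the index prefers `b` (short, paved), then `c`, then `a`, and the
#' greedy route serves all three centers in one trip. All numbers are this
#' package's own synthetic choices.
#'
#' @return an `lm_instance`.
#' @export
fixture_four_centers <- function() {
  cnames <- c("o", "a", "b", "c")
  distance <- matrix(c(
     0, 30, 20, 45,
    30,  0, 25, 35,
    22, 26,  0, 15,
    44, 34, 16,  0), 4, 4, byrow = TRUE, dimnames = list(cnames, cnames))
  cond <- matrix("fully paved", 4, 4, dimnames = list(cnames, cnames))
  cond["o", "a"] <- cond["a", "o"] <- "dirt road (good quality)"
  cond["a", "c"] <- cond["c", "a"] <- "partially paved"
  centers <- data.frame(
    name = cnames, center_type = c("district store", rep("health center", 3)),
    cold_capacity = c(50, 10, 10, 10), dry_capacity = c(200, 40, 40, 40),
    is_depot = c(TRUE, FALSE, FALSE, FALSE))
  products <- data.frame(
    name = c("measles", "syringes 0.5ml"),
    unit_volume = c(0.02, 0.01), doses_per_vial = c(10L, 1L),
    requires_cold = c(TRUE, FALSE), available_supply = c(500, 800))
  vehicles <- data.frame(
    name = "4x4", condition_class = "very reliable", velocity = 60,
    cold_capacity = 25, dry_capacity = 60, fuel_consumption = 0.12,
    fuel_price = 1.5, per_diem = 500)
  demand <- matrix(c(0, 0, 100, 120, 150, 180, 80, 90), 4, 2, byrow = TRUE,
                   dimnames = list(cnames, products$name))
  parameters <- list(
    run_description = "four-center walkthrough fixture",
    start_location = "o", start_time = "08:00", max_route_hours = 8,
    dropoff_time = 0.25, transit_weight_raw = 5)
  instance(centers, products, vehicles, distance, cond, demand, parameters)
}
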