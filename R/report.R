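#' Post-hoc route costs
#'
#' Costs are informational and computed after optimization, never inside the
#' objective: fuel cost is the route distance times the vehicle's consumption
#' (L/km) times the fuel price, and one personnel per diem is charged per
#' executed route (a route fits in one working day by construction).
#'
#' @param route one element of `solution$routes` (must be closed, i.e. end at
#'   the depot).
#' @param inst the `lm_instance`.
#' @return list with `distance_km`, `fuel_cost`, `per_diem_cost`.
#' @export
route_costs <- function(route, inst) {
  sq <- route$sequence
  if (sq[length(sq)] != depot_name(inst))
    stop("route is not closed: it must end at the depot", call. = FALSE)
  ci <- .center_index(inst, sq)
  vi <- .vehicle_index(inst, route$vehicle)
  km <- sum(inst$roads$distance[cbind(ci[-length(ci)], ci[-1])])
  list(distance_km = km,
       fuel_cost = km * inst$vehicles$fuel_consumption[vi] *
         inst$vehicles$fuel_price[vi],
       per_diem_cost = inst$vehicles$per_diem[vi])
}

#' Disaggregate grouped deliveries into per-product quantities
#'
#' The optimization works on two volume classes; the report restores the
#' product detail. Each center served by a single route receives its full
#' scaled per-product demand on that route. If a center's volume is split
#' across routes (possible in exact-model solutions), products are assigned
#' to routes greedily by volume, largest products first, filling each route's
#' delivered volume in route order; boundary units may then be split
#' fractionally so that volumes reconcile exactly.
#'
#' @param solution an `lm_solution`.
#' @param grouped the `lm_grouped` it solves.
#' @param tol reconciliation tolerance in liters.
#' @return data.frame with `route`, `center`, `product`, `quantity` (doses or
#'   units) and `volume_l`.
#' @export
disaggregate_products <- function(solution, grouped, tol = 1e-6) {
  inst <- grouped$instance
  out <- data.frame(route = integer(), center = character(),
                    product = character(), quantity = numeric(),
                    volume_l = numeric())
  for (cn in unique(solution$deliveries$center)) {
    dl <- solution$deliveries[solution$deliveries$center == cn, , drop = FALSE]
    ci <- .center_index(inst, cn)
    for (class_cold in c(TRUE, FALSE)) {
      pids <- which(as.logical(inst$products$requires_cold) == class_cold &
                    grouped$scaled_demand[ci, ] > 0)
      if (!length(pids)) next
      route_vol <- if (class_cold) dl$cold_volume else dl$dry_volume
      qty <- grouped$scaled_demand[ci, pids]
      vols <- qty * inst$products$unit_volume[pids]
      if (abs(sum(vols) - sum(route_vol)) > tol)
        stop(sprintf(
          "integrity error: %s volume at %s (%.6f L) does not reconcile with deliveries (%.6f L)",
          if (class_cold) "cold" else "dry", cn, sum(vols), sum(route_vol)),
          call. = FALSE)
      # largest products first, fill routes in order
      ord <- order(-vols, pids)
      r_idx <- 1L
      r_left <- route_vol[r_idx]
      for (p in ord) {
        q_left <- qty[p]
        k <- inst$products$unit_volume[pids[p]]
        while (q_left > 1e-12) {
          while (r_left <= 1e-12 && r_idx < length(route_vol)) {
            r_idx <- r_idx + 1L
            r_left <- route_vol[r_idx]
          }
          q_here <- min(q_left, r_left / k)
          if (r_idx == length(route_vol)) q_here <- q_left  # absorb rounding
          out <- rbind(out, data.frame(
            route = dl$route[r_idx], center = cn,
            product = inst$products$name[pids[p]],
            quantity = q_here, volume_l = q_here * k))
          q_left <- q_left - q_here
          r_left <- r_left - q_here * k
        }
      }
    }
  }
  out[order(out$route, out$center, out$product), , drop = FALSE]
}

.parse_hhmm <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))[[1]]
  if (length(m) != 3L) stop("clock time must be HH:MM, got ", sQuote(s),
                            call. = FALSE)
  as.numeric(m[2]) + as.numeric(m[3]) / 60
}

.format_hhmm <- function(hours) {
  days <- floor(hours / 24)
  hours <- hours - 24 * days
  mins <- round(hours * 60)
  sprintf("%02d:%02d%s", mins %/% 60, mins %% 60,
          ifelse(days > 0, sprintf(" (+%dd)", days), ""))
}

#' Clock departure times along a route
#'
#' Converts model departure times (hours from route start) to wall-clock
#' HH:MM, starting from the run's start time; the drop-off time is already
#' included in the model times.
#'
#' @param route one element of `solution$routes`.
#' @param start_time "HH:MM" start of the route.
#' @return character vector of clock times, one per stop in the sequence
#'   (the last entry is the arrival back at the depot).
#' @export
departure_clock_times <- function(route, start_time) {
  .format_hhmm(.parse_hhmm(start_time) + route$depart)
}

#' Assemble the output report tables
#'
#' Builds the two output tables: `routes` (one summary row per route with
#' distance, duration, costs, vehicle condition and capacity utilization,
#' followed by one row per leg with road condition and clock departure time)
#' and `products` (per route and center, the product quantities delivered and
#' the center's utilized cold/dry volume).
#'
#' @param solution an `lm_solution`.
#' @param grouped the `lm_grouped` it solves.
#' @return list with data.frames `routes` and `products`.
#' @export
build_report <- function(solution, grouped) {
  inst <- grouped$instance
  start <- inst$parameters$start_time
  routes <- data.frame(
    route = integer(), row_type = character(), vehicle = character(),
    vehicle_condition = character(), total_distance_km = numeric(),
    duration_h = numeric(), fuel_cost = numeric(), per_diem_cost = numeric(),
    cold_utilization = numeric(), dry_utilization = numeric(),
    run_description = character(), leg_from = character(),
    leg_to = character(), leg_distance_km = numeric(),
    leg_road_condition = character(), depart_time = character())
  for (r in seq_along(solution$routes)) {
    rt <- solution$routes[[r]]
    vi <- .vehicle_index(inst, rt$vehicle)
    costs <- route_costs(rt, inst)
    dl <- solution$deliveries[solution$deliveries$route == r, , drop = FALSE]
    clocks <- departure_clock_times(rt, start)
    blank <- NA_character_
    summary_row <- data.frame(
      route = r, row_type = "summary", vehicle = rt$vehicle,
      vehicle_condition = inst$vehicles$condition_class[vi],
      total_distance_km = costs$distance_km,
      duration_h = rt$duration,
      fuel_cost = costs$fuel_cost, per_diem_cost = costs$per_diem_cost,
      cold_utilization = if (inst$vehicles$cold_capacity[vi] > 0)
        sum(dl$cold_volume) / inst$vehicles$cold_capacity[vi] else 0,
      dry_utilization = if (inst$vehicles$dry_capacity[vi] > 0)
        sum(dl$dry_volume) / inst$vehicles$dry_capacity[vi] else 0,
      run_description = inst$parameters$run_description,
      leg_from = blank, leg_to = blank, leg_distance_km = NA_real_,
      leg_road_condition = blank, depart_time = blank)
    sq <- rt$sequence
    ci <- .center_index(inst, sq)
    legs <- data.frame(
      route = r, row_type = "leg", vehicle = rt$vehicle,
      vehicle_condition = inst$vehicles$condition_class[vi],
      total_distance_km = NA_real_, duration_h = NA_real_,
      fuel_cost = NA_real_, per_diem_cost = NA_real_,
      cold_utilization = NA_real_, dry_utilization = NA_real_,
      run_description = blank,
      leg_from = sq[-length(sq)], leg_to = sq[-1],
      leg_distance_km = inst$roads$distance[cbind(ci[-length(ci)], ci[-1])],
      leg_road_condition = inst$roads$condition[cbind(ci[-length(ci)], ci[-1])],
      depart_time = clocks[-length(clocks)])
    routes <- rbind(routes, summary_row, legs)
  }
  products <- disaggregate_products(solution, grouped)
  if (nrow(products)) {
    ci <- .center_index(inst, products$center)
    products$center_cold_used_l <- grouped$cold_demand[ci]
    products$center_dry_used_l <- grouped$dry_demand[ci]
  } else {
    products$center_cold_used_l <- numeric(0)
    products$center_dry_used_l <- numeric(0)
  }
  list(routes = routes, products = products)
}
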