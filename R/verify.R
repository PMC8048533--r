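#' Independently audit a solution
#'
#' Re-checks a solution against the instance data from first principles,
#' sharing no code with the solvers: every route must start and end at the
#' depot and visit no center twice; every arc must be available; the route
#' duration recomputed from distances, velocities and the drop-off time must
#' respect the maximum; the volumes loaded on each route must fit the
#' vehicle's cold and dry compartments; the deliveries must cover the scaled
#' demand volume of every center exactly; and (for heuristic solutions) no
#' vehicle may run a second route while another vehicle is two or more routes
#' behind (the all-vehicles-before-reuse rule). The reported objective is
#' also recomputed from the arcs.
#'
#' @param solution an `lm_solution`.
#' @param grouped the `lm_grouped` it solves.
#' @param check_vehicle_reuse audit the all-before-reuse rule (default: only
#'   for heuristic solutions; the exact model has one route per vehicle).
#' @param tol feasibility tolerance.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
audit_solution <- function(solution, grouped,
                           check_vehicle_reuse = solution$solver != "mip",
                           tol = 1e-6) {
  inst <- grouped$instance
  bad <- character()
  dep <- depot_name(inst)
  dist <- inst$roads$distance
  avail <- inst$roads$availability
  W <- inst$parameters$dropoff_time
  l <- inst$parameters$max_route_hours

  # demand volumes recomputed from the scaled per-product demand
  kv <- inst$products$unit_volume
  coldp <- as.logical(inst$products$requires_cold)
  need_cold <- as.numeric(grouped$scaled_demand[, coldp, drop = FALSE] %*% kv[coldp])
  need_dry <- as.numeric(grouped$scaled_demand[, !coldp, drop = FALSE] %*% kv[!coldp])
  names(need_cold) <- names(need_dry) <- inst$centers$name

  got_cold <- got_dry <- stats::setNames(numeric(nrow(inst$centers)),
                                         inst$centers$name)
  arc_total <- 0

  for (r in seq_along(solution$routes)) {
    rt <- solution$routes[[r]]
    sq <- rt$sequence
    if (sq[1] != dep || sq[length(sq)] != dep) {
      bad <- c(bad, sprintf("route %d does not start and end at the depot", r))
      next
    }
    inner <- sq[-c(1, length(sq))]
    if (anyDuplicated(inner) || dep %in% inner)
      bad <- c(bad, sprintf("route %d revisits a center", r))
    vi <- match(rt$vehicle, inst$vehicles$name)
    ci <- match(sq, inst$centers$name)
    dur <- 0
    for (k in seq_len(length(ci) - 1L)) {
      if (avail[ci[k], ci[k + 1L]] != 1)
        bad <- c(bad, sprintf("route %d uses unavailable arc %s -> %s",
                              r, sq[k], sq[k + 1L]))
      dur <- dur + dist[ci[k], ci[k + 1L]] / inst$vehicles$velocity[vi]
      if (k < length(ci) - 1L) dur <- dur + W
      arc_total <- arc_total + arc_cost(
        dist[ci[k], ci[k + 1L]] / inst$vehicles$velocity[vi],
        inst$roads$gamma[ci[k], ci[k + 1L]], inst$vehicles$penalty[vi],
        grouped$W_t, grouped$W_p, grouped$means, solution$objective_form)
    }
    if (dur > l + tol)
      bad <- c(bad, sprintf("route %d lasts %.3f h, over the %.3f h limit",
                            r, dur, l))
    dl <- solution$deliveries[solution$deliveries$route == r, , drop = FALSE]
    if (!setequal(dl$center, inner))
      bad <- c(bad, sprintf("route %d deliveries do not match its visits", r))
    if (any(dl$cold_volume < -tol) || any(dl$dry_volume < -tol))
      bad <- c(bad, sprintf("route %d has negative deliveries", r))
    if (sum(dl$cold_volume) > inst$vehicles$cold_capacity[vi] + tol)
      bad <- c(bad, sprintf("route %d cold load exceeds vehicle capacity", r))
    if (sum(dl$dry_volume) > inst$vehicles$dry_capacity[vi] + tol)
      bad <- c(bad, sprintf("route %d dry load exceeds vehicle capacity", r))
    got_cold[dl$center] <- got_cold[dl$center] + dl$cold_volume
    got_dry[dl$center] <- got_dry[dl$center] + dl$dry_volume
  }

  uncovered <- abs(got_cold - need_cold) > tol | abs(got_dry - need_dry) > tol
  if (any(uncovered))
    bad <- c(bad, sprintf("demand coverage mismatch at: %s",
                          paste(names(which(uncovered)), collapse = ", ")))

  if (length(solution$routes) && abs(arc_total - solution$objective) > tol)
    bad <- c(bad, sprintf("reported objective %.8f != recomputed %.8f",
                          solution$objective, arc_total))

  if (check_vehicle_reuse && length(solution$routes)) {
    counts <- table(factor(vapply(solution$routes, `[[`, character(1), "vehicle"),
                           levels = inst$vehicles$name))
    if (max(counts) - min(counts) >= 2)
      bad <- c(bad, "a vehicle was reused before all vehicles were used")
  }

  list(ok = length(bad) == 0L, violations = bad)
}
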