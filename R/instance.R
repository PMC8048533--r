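#' Assemble a district routing instance
#'
#' An instance bundles everything needed to plan one distribution run: the
#' health centers (one of which is the depot), the product catalogue, the
#' fleet, the asymmetric distance matrix, the categorical road conditions,
#' the per-center per-product demand, and the run parameters. Condition
#' labels are mapped to numeric penalties (`gamma` for roads, `beta` for
#' vehicles) and to the arc availability flags at construction time.
#'
#' Construction is deliberately permissive: structural problems (missing
#' depot, dimension mismatches, nonpositive velocities, ...) are reported by
#' [validate_instance()] rather than raised here, so that a user can load a
#' half-finished workbook and see all findings at once. Unknown condition
#' labels are the one exception and raise immediately, since no penalty can
#' be derived for them.
#'
#' @param centers data.frame with columns `name`, `center_type`,
#'   `cold_capacity`, `dry_capacity` (liters), `is_depot` (logical).
#' @param products data.frame with columns `name`, `unit_volume` (liters per
#'   dose/unit), `doses_per_vial`, `requires_cold` (logical),
#'   `available_supply` (units at the depot).
#' @param vehicles data.frame with columns `name`, `condition_class` (see
#'   [VEHICLE_CONDITIONS]), `velocity` (km/h), `cold_capacity`,
#'   `dry_capacity` (liters), `fuel_consumption` (L/km), `fuel_price`
#'   (currency/L), `per_diem` (currency per route-day).
#' @param distance numeric |C| x |C| matrix of km, rows = origin; need not be
#'   symmetric.
#' @param road_condition character |C| x |C| matrix of labels from
#'   [ROAD_CONDITIONS].
#' @param demand numeric |C| x |P| matrix of units/doses.
#' @param parameters list with `run_description`, `start_location` (depot
#'   name), `start_time` ("HH:MM"), `max_route_hours` (l), `dropoff_time`
#'   (W, hours), `transit_weight_raw` (0..10), and optionally
#'   `objective_form` ("printed" or "increasing", default "printed").
#' @param road_penalties,vehicle_penalties optional overrides for the
#'   condition-to-penalty scales (see [map_road_condition()]).
#' @return an object of class `lm_instance`.
#' @seealso [validate_instance()], [read_instance()], [generate_instance()]
#' @export
instance <- function(centers, products, vehicles, distance, road_condition,
                     demand, parameters,
                     road_penalties = .default_road_penalties,
                     vehicle_penalties = .default_vehicle_penalties) {
  centers <- as.data.frame(centers)
  products <- as.data.frame(products)
  vehicles <- as.data.frame(vehicles)
  distance <- as.matrix(distance)
  road_condition <- as.matrix(road_condition)
  demand <- as.matrix(demand)

  road <- map_road_condition(as.vector(road_condition), road_penalties)
  gamma <- matrix(road$gamma, nrow(road_condition), ncol(road_condition))
  availability <- matrix(as.integer(road$available),
                         nrow(road_condition), ncol(road_condition))
  vehicles$penalty <- map_vehicle_condition(vehicles$condition_class,
                                            vehicle_penalties)

  dimnames(distance) <- list(centers$name, centers$name)
  dimnames(gamma) <- dimnames(availability) <-
    dimnames(road_condition) <- dimnames(distance)
  dimnames(demand) <- list(centers$name, products$name)

  parameters$objective_form <- match.arg(
    parameters$objective_form %||% "printed", c("printed", "increasing"))
  parameters$transit_weight_raw <- as.numeric(parameters$transit_weight_raw)
  w <- normalize_weights(parameters$transit_weight_raw)
  parameters$W_t <- w[["W_t"]]
  parameters$W_p <- w[["W_p"]]

  structure(
    list(centers = centers, products = products, vehicles = vehicles,
         roads = list(distance = distance, condition = road_condition,
                      gamma = gamma, availability = availability),
         demand = demand, parameters = parameters),
    class = "lm_instance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lm_instance <- function(x, ...) {
  cat(sprintf("district routing instance: %d centers (depot: %s), %d products, %d vehicles\n",
              nrow(x$centers), depot_name(x), nrow(x$products), nrow(x$vehicles)))
  cat(sprintf("  route limit %.2g h, drop-off %.2g h, weights W_t=%.2f W_p=%.2f (%s objective)\n",
              x$parameters$max_route_hours, x$parameters$dropoff_time,
              x$parameters$W_t, x$parameters$W_p, x$parameters$objective_form))
  invisible(x)
}

#' Name of the depot (supply node) of an instance
#' @param inst an `lm_instance`.
#' @return the depot center name.
#' @export
depot_name <- function(inst) {
  d <- inst$centers$name[which(inst$centers$is_depot)]
  if (length(d) != 1L) stop("instance does not have exactly one depot", call. = FALSE)
  d
}

.center_index <- function(inst, name) {
  i <- match(name, inst$centers$name)
  if (anyNA(i)) stop("unknown center name(s): ",
                     paste(sQuote(name[is.na(i)]), collapse = ", "), call. = FALSE)
  i
}

.vehicle_index <- function(inst, name) {
  v <- match(name, inst$vehicles$name)
  if (anyNA(v)) stop("unknown vehicle name(s): ",
                     paste(sQuote(name[is.na(v)]), collapse = ", "), call. = FALSE)
  v
}

#' Transit time between two centers with a given vehicle
#'
#' Transit times are derived from the distance matrix and the vehicle's
#' average velocity, `h = distance / velocity`, in hours. The diagonal is
#' zero by definition.
#'
#' @param inst an `lm_instance`.
#' @param i,j center names (or integer indices).
#' @param v vehicle name (or integer index).
#' @return transit time in hours.
#' @export
transit_time <- function(inst, i, j, v) {
  ii <- if (is.character(i)) .center_index(inst, i) else i
  jj <- if (is.character(j)) .center_index(inst, j) else j
  vv <- if (is.character(v)) .vehicle_index(inst, v) else v
  if (ii == jj) return(0)
  inst$roads$distance[ii, jj] / inst$vehicles$velocity[vv]
}

#' Transit-time matrix for one vehicle (hours), zero diagonal
#' @param inst an `lm_instance`.
#' @param v vehicle name or index.
#' @return |C| x |C| numeric matrix.
#' @export
transit_matrix <- function(inst, v) {
  vv <- if (is.character(v)) .vehicle_index(inst, v) else v
  h <- inst$roads$distance / inst$vehicles$velocity[vv]
  diag(h) <- 0
  h
}

#' Scaling means of an instance
#'
#' Means used to bring transit times, penalties, capacities and velocities
#' onto a comparable scale inside the objective and the construction indices:
#' \deqn{\mu_h = \sum_v \sum_{i,j} 2 h_{ijv} / (|V| |C|^2)}
#' with the factor 2 applied as defined for the model (disable with
#' `double_mean = FALSE`); \eqn{\mu_\beta, \mu_\gamma} are plain means of the
#' vehicle and road penalties (all |C|^2 road entries included); and
#' \eqn{\mu_{cr}, \mu_{cd}, \mu_v} are the mean cold capacity, dry capacity
#' and velocity over the fleet.
#'
#' @param inst an `lm_instance`.
#' @param double_mean logical; keep the factor 2 in `mu_h` (default `TRUE`).
#' @return a list of class `lm_means` with elements `mu_h`, `mu_beta`,
#'   `mu_gamma`, `mu_cr`, `mu_cd`, `mu_v`.
#' @export
compute_means <- function(inst, double_mean = TRUE) {
  nC <- nrow(inst$centers)
  nV <- nrow(inst$vehicles)
  if (nC < 1L || nV < 1L)
    stop("degenerate instance: needs at least one center and one vehicle",
         call. = FALSE)
  hsum <- 0
  for (v in seq_len(nV)) hsum <- hsum + sum(transit_matrix(inst, v))
  mu_h <- (if (double_mean) 2 else 1) * hsum / (nV * nC^2)
  structure(list(
    mu_h = mu_h,
    mu_beta = mean(inst$vehicles$penalty),
    mu_gamma = mean(inst$roads$gamma),
    mu_cr = mean(inst$vehicles$cold_capacity),
    mu_cd = mean(inst$vehicles$dry_capacity),
    mu_v = mean(inst$vehicles$velocity)
  ), class = "lm_means")
}

.finding <- function(severity, message) {
  data.frame(severity = severity, message = message)
}

#' Validate an instance
#'
#' Returns a data.frame of findings rather than raising: structural defects
#' (missing or duplicated depot, dimension mismatches, nonpositive
#' velocities, negative quantities, demand recorded at the depot) are
#' `error` findings that block solving; conditions the tool is designed to
#' tolerate -- demand volume exceeding a center's storage capacity, total
#' demand exceeding available supply (demand will be scaled back), centers
#' unreachable over available roads -- are `warning` findings and the
#' optimization can still be run.
#'
#' @param inst an `lm_instance`.
#' @return data.frame with columns `severity` ("error"/"warning") and
#'   `message`; zero rows for a clean instance.
#' @export
validate_instance <- function(inst) {
  f <- .finding(character(), character())
  nC <- nrow(inst$centers)
  nP <- nrow(inst$products)

  ndep <- sum(inst$centers$is_depot)
  if (ndep != 1L)
    f <- rbind(f, .finding("error", sprintf(
      "instance must have exactly one depot center, found %d", ndep)))
  if (!inst$parameters$start_location %in% inst$centers$name)
    f <- rbind(f, .finding("error", sprintf(
      "start_location %s is not a known center", sQuote(inst$parameters$start_location))))
  else if (ndep == 1L &&
           inst$parameters$start_location != inst$centers$name[inst$centers$is_depot])
    f <- rbind(f, .finding("error",
      "start_location does not match the center flagged as depot"))

  if (anyDuplicated(inst$centers$name))
    f <- rbind(f, .finding("error", "duplicated center names"))

  for (m in c("distance", "condition", "gamma", "availability")) {
    if (!all(dim(inst$roads[[m]]) == c(nC, nC)))
      f <- rbind(f, .finding("error", sprintf(
        "%s matrix is %dx%d, expected %dx%d", m,
        nrow(inst$roads[[m]]), ncol(inst$roads[[m]]), nC, nC)))
  }
  if (!all(dim(inst$demand) == c(nC, nP)))
    f <- rbind(f, .finding("error", sprintf(
      "demand matrix is %dx%d, expected %dx%d (centers x products)",
      nrow(inst$demand), ncol(inst$demand), nC, nP)))
  if (nrow(f[f$severity == "error", ]) > 0L) return(f)

  if (anyNA(inst$roads$distance) || any(inst$roads$distance < 0))
    f <- rbind(f, .finding("error", "distances must be nonnegative and complete (no blanks)"))
  if (anyNA(inst$demand) || any(inst$demand < 0))
    f <- rbind(f, .finding("error", "demand entries must be nonnegative and complete"))
  if (any(inst$vehicles$velocity <= 0))
    f <- rbind(f, .finding("error", "vehicle velocities must be positive"))
  if (any(inst$vehicles$cold_capacity < 0) || any(inst$vehicles$dry_capacity < 0))
    f <- rbind(f, .finding("error", "vehicle capacities must be nonnegative"))
  if (any(inst$centers$cold_capacity < 0) || any(inst$centers$dry_capacity < 0))
    f <- rbind(f, .finding("error", "center storage capacities must be nonnegative"))
  if (any(inst$products$unit_volume <= 0))
    f <- rbind(f, .finding("error", "product unit volumes must be positive"))
  if (any(inst$products$available_supply < 0))
    f <- rbind(f, .finding("error", "available supply must be nonnegative"))
  w <- inst$parameters$transit_weight_raw
  if (is.na(w) || w < 0 || w > 10)
    f <- rbind(f, .finding("error", "transit-time weight must be in [0, 10]"))
  if (inst$parameters$max_route_hours <= 0)
    f <- rbind(f, .finding("error", "maximum route duration must be positive"))
  if (inst$parameters$dropoff_time < 0)
    f <- rbind(f, .finding("error", "drop-off time must be nonnegative"))
  if (nrow(f[f$severity == "error", ]) > 0L) return(f)

  dep <- .center_index(inst, depot_name(inst))
  if (any(inst$demand[dep, ] != 0))
    f <- rbind(f, .finding("error", "demand at the depot row must be zero"))

  # storage-capacity warnings: demand volume vs center storage, per class
  vol <- .demand_volumes(inst$demand, inst$products)
  for (i in seq_len(nrow(inst$centers))) {
    if (vol$cold[i] > inst$centers$cold_capacity[i] + 1e-9)
      f <- rbind(f, .finding("warning", sprintf(
        "cold demand volume at %s (%.2f L) exceeds its cold storage capacity (%.2f L)",
        inst$centers$name[i], vol$cold[i], inst$centers$cold_capacity[i])))
    if (vol$dry[i] > inst$centers$dry_capacity[i] + 1e-9)
      f <- rbind(f, .finding("warning", sprintf(
        "dry demand volume at %s (%.2f L) exceeds its dry storage capacity (%.2f L)",
        inst$centers$name[i], vol$dry[i], inst$centers$dry_capacity[i])))
  }

  # supply shortfall: demand will be scaled back; recommend repeat deliveries
  short <- colSums(inst$demand) > inst$products$available_supply + 1e-9
  for (p in which(short))
    f <- rbind(f, .finding("warning", sprintf(
      "total demand for %s (%g) exceeds available supply (%g); demand will be scaled back and a repeat delivery is recommended",
      inst$products$name[p], colSums(inst$demand)[p],
      inst$products$available_supply[p])))

  # reachability over available arcs (directed, from depot)
  reach <- .reachable_from(inst$roads$availability, dep)
  unreachable <- setdiff(which(!reach), dep)
  for (i in unreachable)
    f <- rbind(f, .finding("warning", sprintf(
      "center %s is not reachable from the depot over available roads",
      inst$centers$name[i])))
  f
}

# per-center cold/dry demand volumes (liters) for a demand table in units
.demand_volumes <- function(demand, products) {
  kv <- products$unit_volume
  cold <- as.logical(products$requires_cold)
  list(cold = as.numeric(demand[, cold, drop = FALSE] %*% kv[cold]),
       dry = as.numeric(demand[, !cold, drop = FALSE] %*% kv[!cold]))
}

.reachable_from <- function(avail, start) {
  n <- nrow(avail)
  seen <- rep(FALSE, n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(avail[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}
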