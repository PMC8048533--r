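# Independent oracles used across the suite. These re-derive everything from
# the raw instance tables and share no code with the package's solvers.

# arc cost re-typed from the model definition
oracle_arc_cost <- function(h, gamma, beta, W_t, W_p, means, form) {
  s <- if (form == "printed") -1 else 1
  sc <- function(x, mu) if (mu > 0) x / mu else 1
  W_t * exp(s * sc(h, means$mu_h)) +
    W_p * (exp(s * sc(gamma, means$mu_gamma)) + exp(s * sc(beta, means$mu_beta)))
}

oracle_means <- function(inst) {
  nC <- nrow(inst$centers); nV <- nrow(inst$vehicles)
  hs <- 0
  for (v in seq_len(nV)) {
    h <- inst$roads$distance / inst$vehicles$velocity[v]
    diag(h) <- 0
    hs <- hs + sum(h)
  }
  list(mu_h = 2 * hs / (nV * nC^2),
       mu_beta = sum(inst$vehicles$penalty) / nV,
       mu_gamma = sum(inst$roads$gamma) / nC^2,
       mu_cr = mean(inst$vehicles$cold_capacity),
       mu_cd = mean(inst$vehicles$dry_capacity),
       mu_v = mean(inst$vehicles$velocity))
}

.perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x))
    for (p in .perms(x[-k])) out[[length(out) + 1L]] <- c(x[k], p)
  out
}

# cost of one vehicle's route over an ordered center set, Inf if infeasible:
# availability on every arc, compartment capacities, and after every drop-off
# the vehicle must still make it back to the depot within l
oracle_route_cost <- function(inst, grouped, means, v, dep, ord, form) {
  if (!length(ord)) return(0)
  if (sum(grouped$cold_demand[ord]) > inst$vehicles$cold_capacity[v] + 1e-9 ||
      sum(grouped$dry_demand[ord]) > inst$vehicles$dry_capacity[v] + 1e-9)
    return(Inf)
  W <- inst$parameters$dropoff_time
  l <- inst$parameters$max_route_hours
  vel <- inst$vehicles$velocity[v]
  path <- c(dep, ord, dep)
  t <- 0
  cost <- 0
  for (k in seq_len(length(path) - 1L)) {
    i <- path[k]; j <- path[k + 1L]
    if (inst$roads$availability[i, j] != 1) return(Inf)
    h <- inst$roads$distance[i, j] / vel
    cost <- cost + oracle_arc_cost(h, inst$roads$gamma[i, j],
                                   inst$vehicles$penalty[v],
                                   grouped$W_t, grouped$W_p, means, form)
    t <- t + h
    if (j != dep) {
      t <- t + W
      if (t + inst$roads$distance[j, dep] / vel > l + 1e-9) return(Inf)
    }
  }
  if (t > l + 1e-9) return(Inf)
  cost
}

# exhaustive optimum over all assignments of demand centers to vehicles (one
# route per vehicle, unused vehicles allowed) and all visit orders
brute_force_optimum <- function(grouped, form) {
  inst <- grouped$instance
  means <- oracle_means(inst)
  dep <- which(inst$centers$is_depot)
  targets <- which(grouped$cold_demand + grouped$dry_demand > 1e-12)
  nV <- nrow(inst$vehicles)
  if (!length(targets)) return(0)
  m <- length(targets)
  assign_grid <- as.matrix(expand.grid(rep(list(seq_len(nV)), m)))
  best <- Inf
  for (a in seq_len(nrow(assign_grid))) {
    total <- 0
    for (v in seq_len(nV)) {
      set <- targets[assign_grid[a, ] == v]
      if (!length(set)) next
      cv <- Inf
      for (ord in .perms(set)) {
        c1 <- oracle_route_cost(inst, grouped, means, v, dep, ord, form)
        if (c1 < cv) cv <- c1
      }
      total <- total + cv
      if (total >= best) break
    }
    if (total < best) best <- total
  }
  best
}

# generator settings for the exhaustively checkable suite: small, ample
# capacity and time, every road passable
oracle_suite_spec <- function(seed, n_centers, n_vehicles) {
  generator_spec(
    n_centers = n_centers, n_vehicles = n_vehicles, n_products = 5,
    field_km = 80, capacity_tightness = 0.35, max_route_hours = 10,
    road_condition_probs = c(
      "fully paved" = 0.35, "partially paved" = 0.25,
      "dirt road (good quality)" = 0.2, "dirt road (rough quality)" = 0.1,
      "boat access only" = 0.05, "foot access only" = 0.05,
      "not accessible" = 0),
    seed = seed)
}
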