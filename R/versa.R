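#' Vehicle selection index
#'
#' First stage of the two-stage construction rule: vehicles are ranked by
#' \deqn{e^{-\beta_v/\mu_\beta} + e^{c_{vr}/\mu_{cr}} + e^{c_{vd}/\mu_{cd}} + e^{v_v/\mu_v}}
#' and the vehicle with the largest index is assigned a route next. The index
#' prefers reliable vehicles (low penalty) with large cold and dry capacities
#' and high velocity.
#'
#' @param vehicle one row of the vehicles table (anything with `penalty`,
#'   `cold_capacity`, `dry_capacity`, `velocity`).
#' @param means an `lm_means` object.
#' @return numeric score; larger is better.
#' @export
vehicle_index <- function(vehicle, means) {
  exp(-.scaled(vehicle$penalty, means$mu_beta)) +
    exp(.scaled(vehicle$cold_capacity, means$mu_cr)) +
    exp(.scaled(vehicle$dry_capacity, means$mu_cd)) +
    exp(.scaled(vehicle$velocity, means$mu_v))
}

#' Next-center selection index
#'
#' Second stage of the construction rule: from the current center `i`, the
#' next center `j` for vehicle `v` is the feasible candidate maximizing
#' \deqn{W_t e^{-h_{ijv}/\mu_h} + W_p e^{-\gamma_{ij}/\mu_\gamma}.}
#' The index prefers nearby centers and low-penalty roads.
#'
#' @param grouped an `lm_grouped`.
#' @param i,j center names or indices.
#' @param v vehicle name or index.
#' @return numeric score; larger is better.
#' @export
node_index <- function(grouped, i, j, v) {
  inst <- grouped$instance
  ii <- if (is.character(i)) .center_index(inst, i) else i
  jj <- if (is.character(j)) .center_index(inst, j) else j
  vv <- if (is.character(v)) .vehicle_index(inst, v) else v
  h <- transit_time(inst, ii, jj, vv)
  grouped$W_t * exp(-.scaled(h, grouped$means$mu_h)) +
    grouped$W_p * exp(-.scaled(inst$roads$gamma[ii, jj], grouped$means$mu_gamma))
}

# ---------------------------------------------------------------------------
# solver context: everything precomputed and index-based

.solver_context <- function(grouped, objective_form = NULL) {
  inst <- grouped$instance
  objective_form <- objective_form %||% inst$parameters$objective_form
  nC <- nrow(inst$centers)
  nV <- nrow(inst$vehicles)
  dep <- .center_index(inst, depot_name(inst))
  h <- lapply(seq_len(nV), function(v) transit_matrix(inst, v))
  cost <- lapply(seq_len(nV), function(v)
    arc_cost_matrix(grouped, v, objective_form))
  nidx <- lapply(seq_len(nV), function(v)
    grouped$W_t * exp(-.scaled(h[[v]], grouped$means$mu_h)) +
      grouped$W_p * exp(-.scaled(inst$roads$gamma, grouped$means$mu_gamma)))
  vscore <- vapply(seq_len(nV), function(v)
    vehicle_index(inst$vehicles[v, ], grouped$means), numeric(1))
  list(
    grouped = grouped, inst = inst, form = objective_form,
    nC = nC, nV = nV, dep = dep,
    h = h, cost = cost, nidx = nidx,
    avail = inst$roads$availability,
    D_r = as.numeric(grouped$cold_demand),
    D_d = as.numeric(grouped$dry_demand),
    cap_r = inst$vehicles$cold_capacity,
    cap_d = inst$vehicles$dry_capacity,
    l = inst$parameters$max_route_hours,
    W = inst$parameters$dropoff_time,
    vehicle_order = order(-vscore, seq_len(nV)),
    targets = which(grouped$cold_demand + grouped$dry_demand > 1e-12)
  )
}

.fresh_state <- function(ctx, v) {
  list(v = v, seq = ctx$dep, time = 0,
       rem_r = ctx$cap_r[v], rem_d = ctx$cap_d[v])
}

# availability, capacity and time checks for extending a route state by j;
# the time check requires that after dropping off at j the vehicle can still
# return to the depot within l, and the return arc must itself be available
.feasible <- function(ctx, state, j) {
  last <- state$seq[length(state$seq)]
  v <- state$v
  if (ctx$avail[last, j] != 1) return("availability")
  if (ctx$avail[j, ctx$dep] != 1) return("return-availability")
  if (ctx$D_r[j] > state$rem_r + 1e-9) return("cold-capacity")
  if (ctx$D_d[j] > state$rem_d + 1e-9) return("dry-capacity")
  if (state$time + ctx$h[[v]][last, j] + ctx$W + ctx$h[[v]][j, ctx$dep] >
      ctx$l + 1e-9) return("time")
  NA_character_
}

.extend <- function(ctx, state, j) {
  last <- state$seq[length(state$seq)]
  state$time <- state$time + ctx$h[[state$v]][last, j] + ctx$W
  state$rem_r <- state$rem_r - ctx$D_r[j]
  state$rem_d <- state$rem_d - ctx$D_d[j]
  state$seq <- c(state$seq, j)
  state
}

#' Check whether a route can feasibly be extended to a center
#'
#' Applies the feasibility rules of the construction heuristic: the arc from
#' the route's current endpoint to `j` must be available, the center's cold
#' and dry demand volumes must fit the vehicle's remaining capacities, and
#' after the drop-off at `j` the vehicle must still be able to return to the
#' depot (over an available arc) within the maximum route duration.
#'
#' @param state a route state as returned by [route_state()].
#' @param j candidate center (name or index), not yet served.
#' @param grouped an `lm_grouped`.
#' @return list with `ok` (logical) and `reason` (`NA` when accepted,
#'   otherwise the first violated rule: "availability",
#'   "return-availability", "cold-capacity", "dry-capacity" or "time").
#' @export
feasible_extension <- function(state, j, grouped) {
  ctx <- attr(state, "ctx") %||% .solver_context(grouped)
  jj <- if (is.character(j)) .center_index(grouped$instance, j) else j
  reason <- .feasible(ctx, state, jj)
  list(ok = is.na(reason), reason = reason)
}

#' Create a fresh route state for a vehicle
#'
#' @param grouped an `lm_grouped`.
#' @param v vehicle name or index.
#' @return a route state: the vehicle at the depot with full capacities at
#'   time zero.
#' @export
route_state <- function(grouped, v) {
  ctx <- .solver_context(grouped)
  vv <- if (is.character(v)) .vehicle_index(grouped$instance, v) else v
  s <- .fresh_state(ctx, vv)
  attr(s, "ctx") <- ctx
  s
}

# ---------------------------------------------------------------------------
# greedy construction

# complete a partial assignment greedily; returns list(cost, routes, ok).
# routes entries: list(v = vehicle index, seq = center indices incl. both
# depot endpoints). `state` is an open route state or NULL, `cycle_pos` the
# number of vehicle slots already consumed (for the all-before-reuse cycle).
.greedy_complete <- function(ctx, routes, state, unserved, cost, cycle_pos) {
  n_slots_max <- cycle_pos + length(unserved) * max(ctx$nV, 1L) + ctx$nV
  repeat {
    if (length(unserved) == 0L) {
      if (!is.null(state) && length(state$seq) > 1L) {
        last <- state$seq[length(state$seq)]
        cost <- cost + ctx$cost[[state$v]][last, ctx$dep]
        routes[[length(routes) + 1L]] <- list(v = state$v,
                                              seq = c(state$seq, ctx$dep))
      }
      return(list(cost = cost, routes = routes, ok = TRUE, unserved = unserved))
    }
    if (is.null(state)) {
      v <- ctx$vehicle_order[(cycle_pos %% ctx$nV) + 1L]
      cycle_pos <- cycle_pos + 1L
      if (cycle_pos > n_slots_max)
        return(list(cost = Inf, routes = routes, ok = FALSE, unserved = unserved))
      state <- .fresh_state(ctx, v)
    }
    # best feasible extension by node index; ties by center order
    last <- state$seq[length(state$seq)]
    best <- 0L
    best_score <- -Inf
    for (j in unserved) {
      if (!is.na(.feasible(ctx, state, j))) next
      sc <- ctx$nidx[[state$v]][last, j]
      if (sc > best_score + 1e-15) {
        best <- j
        best_score <- sc
      }
    }
    if (best == 0L) {
      # close (or abandon an empty) route and move to the next vehicle;
      # if a whole cycle of vehicles makes no progress the rest is unservable
      if (length(state$seq) > 1L) {
        cost <- cost + ctx$cost[[state$v]][last, ctx$dep]
        routes[[length(routes) + 1L]] <- list(v = state$v,
                                              seq = c(state$seq, ctx$dep))
        state <- NULL
      } else {
        state <- NULL
        if (.no_vehicle_can_start(ctx, unserved))
          return(list(cost = Inf, routes = routes, ok = FALSE,
                      unserved = unserved))
      }
    } else {
      cost <- cost + ctx$cost[[state$v]][last, best]
      state <- .extend(ctx, state, best)
      unserved <- setdiff(unserved, best)
    }
  }
}

.no_vehicle_can_start <- function(ctx, unserved) {
  for (v in seq_len(ctx$nV)) {
    s <- .fresh_state(ctx, v)
    for (j in unserved) if (is.na(.feasible(ctx, s, j))) return(FALSE)
  }
  TRUE
}

#' Construct a feasible solution with the two-stage index rule
#'
#' Vehicles are sorted by [vehicle_index()] (best first) and each in turn is
#' given a route built by repeatedly adding the feasible unserved center with
#' the largest [node_index()]; when no center fits, the route closes (returns
#' to the depot) and the next vehicle starts. All vehicles receive a route
#' before any vehicle is reused for an additional route. Construction stops
#' when every center with positive demand has been served.
#'
#' @param grouped an `lm_grouped`.
#' @param vehicle_order optional integer or character vector overriding the
#'   index-based vehicle order.
#' @param objective_form "printed" or "increasing"; defaults to the
#'   instance's configured form (the greedy rule itself always maximizes the
#'   index; the form only affects the reported objective).
#' @return an `lm_solution`.
#' @export
construct_greedy <- function(grouped, vehicle_order = NULL,
                             objective_form = NULL) {
  ctx <- .solver_context(grouped, objective_form)
  if (!is.null(vehicle_order)) {
    vo <- if (is.character(vehicle_order))
      .vehicle_index(grouped$instance, vehicle_order) else vehicle_order
    stopifnot(length(vo) == ctx$nV, !anyDuplicated(vo))
    ctx$vehicle_order <- vo
  }
  res <- .greedy_complete(ctx, list(), NULL, ctx$targets, 0, 0L)
  if (!res$ok)
    stop("no vehicle can serve center(s): ",
         paste(ctx$inst$centers$name[res$unserved], collapse = ", "),
         call. = FALSE)
  .build_solution(ctx, res$routes, res$cost, solver = "greedy")
}

# ---------------------------------------------------------------------------
# MST lower bound

# symmetric matrix of the cheapest way to connect two centers: min over
# vehicles and both directions of the arc cost, Inf when no available arc
.min_connect_matrix <- function(ctx, nodes) {
  n <- length(nodes)
  m <- matrix(Inf, n, n)
  for (v in seq_len(ctx$nV)) {
    cv <- ctx$cost[[v]][nodes, nodes, drop = FALSE]
    cv[ctx$avail[nodes, nodes, drop = FALSE] != 1] <- Inf
    m <- pmin(m, cv, t(cv))
  }
  diag(m) <- Inf
  m
}

# Prim's algorithm on a dense symmetric cost matrix; disconnected inputs
# yield the minimum spanning forest weight with attr(connected) = FALSE
.prim_weight <- function(m) {
  n <- nrow(m)
  if (n <= 1L) return(structure(0, connected = TRUE))
  in_tree <- rep(FALSE, n)
  key <- rep(Inf, n)
  in_tree[1L] <- TRUE
  key <- m[1L, ]
  total <- 0
  connected <- TRUE
  for (k in seq_len(n - 1L)) {
    key[in_tree] <- Inf
    u <- which.min(key)
    if (!is.finite(key[u])) {
      connected <- FALSE   # start a new component at no cost
      u <- which(!in_tree)[1L]
    } else {
      total <- total + key[u]
    }
    in_tree[u] <- TRUE
    key <- pmin(key, m[u, ])
  }
  structure(total, connected = connected)
}

#' Minimum-spanning-tree lower bound on the remaining routing cost
#'
#' Any feasible completion must connect every unserved center to the depot
#' (and to the current route endpoint, if a route is open) using arcs whose
#' costs are all positive, so its arc set spans the node set and its cost is
#' at least the weight of a minimum spanning tree on the complete undirected
#' graph whose edge costs are the cheapest available connection (minimum over
#' vehicles and both directions of the arc cost under the active objective
#' form).
#'
#' @param grouped an `lm_grouped`.
#' @param nodes centers (names or indices) to span; typically the unserved
#'   centers plus the depot.
#' @param objective_form "printed" or "increasing".
#' @return the MST weight; if the availability graph restricted to `nodes`
#'   is disconnected the value is the minimum spanning forest weight and
#'   carries `attr(, "connected") = FALSE` (no feasible completion exists).
#' @export
mst_lower_bound <- function(grouped, nodes, objective_form = NULL) {
  ctx <- .solver_context(grouped, objective_form)
  nn <- if (is.character(nodes)) .center_index(grouped$instance, nodes) else nodes
  .prim_weight(.min_connect_matrix(ctx, unique(nn)))
}

# ---------------------------------------------------------------------------
# elite-set branch-and-bound

.node_bound <- function(ctx, node) {
  endpoint <- node$state$seq[length(node$state$seq)]
  nodes <- unique(c(node$unserved, endpoint, ctx$dep))
  node$cost + as.numeric(.prim_weight(.min_connect_matrix(ctx, nodes)))
}

.node_children <- function(ctx, node) {
  children <- list()
  st <- node$state
  last <- st$seq[length(st$seq)]
  cand <- node$unserved[vapply(node$unserved, function(j)
    is.na(.feasible(ctx, st, j)), logical(1))]
  if (length(cand)) {
    sc <- vapply(cand, function(j) ctx$nidx[[st$v]][last, j], numeric(1))
    cand <- cand[order(-sc, cand)]
    for (j in cand) {
      child <- node
      child$cost <- node$cost + ctx$cost[[st$v]][last, j]
      child$state <- .extend(ctx, st, j)
      child$unserved <- setdiff(node$unserved, j)
      child$skips <- 0L
      children[[length(children) + 1L]] <- child
    }
  }
  if (length(st$seq) > 1L) {
    # close the open route, hand over to the next vehicle in the cycle
    child <- node
    child$cost <- node$cost + ctx$cost[[st$v]][last, ctx$dep]
    child$routes <- c(node$routes, list(list(v = st$v, seq = c(st$seq, ctx$dep))))
    child$cycle_pos <- node$cycle_pos + 1L
    # reusing a vehicle (second cycle round) is only allowed if no vehicle
    # was left unused by choice (all-vehicles-before-reuse)
    if (child$cycle_pos < ctx$nV || !isTRUE(node$free_skip)) {
      child$state <- .fresh_state(ctx,
        ctx$vehicle_order[(child$cycle_pos %% ctx$nV) + 1L])
      child$skips <- 0L
      children[[length(children) + 1L]] <- child
    }
  } else if (node$skips < ctx$nV - 1L &&
             (node$cycle_pos < ctx$nV || length(cand) == 0L)) {
    # leave this vehicle unused this round: free choice in the first round
    # (arc costs are vehicle-dependent), forced when nothing fits
    child <- node
    child$cycle_pos <- node$cycle_pos + 1L
    if (length(cand) > 0L) child$free_skip <- TRUE
    if (child$cycle_pos < ctx$nV || !isTRUE(child$free_skip)) {
      child$state <- .fresh_state(ctx,
        ctx$vehicle_order[(child$cycle_pos %% ctx$nV) + 1L])
      child$skips <- node$skips + 1L
      children[[length(children) + 1L]] <- child
    }
  }
  children
}

#' Elite-set branch-and-bound around the index heuristic
#'
#' Builds one initial branch per feasible first center of the top-indexed
#' vehicle (plus, with several vehicles, one branch deferring that vehicle),
#' completes each branch greedily to an incumbent (depth evaluation), selects
#' an elite set of 12% of the branches -- half by best incumbent, half by
#' largest uncertainty (incumbent minus local lower bound) -- and explores
#' branches depth-first with children ordered by decreasing [node_index()],
#' elite branches first, round-robin with a fixed expansion quantum, pruning
#' any node whose committed cost plus the [mst_lower_bound()] over its
#' unserved centers reaches the best incumbent. The greedy solution is the
#' initial incumbent, so the result is never worse than [construct_greedy()].
#'
#' @param grouped an `lm_grouped`.
#' @param budget_s time budget in seconds (default 120; `Inf` explores the
#'   whole tree and proves optimality over the heuristic's solution space).
#' @param objective_form "printed" or "increasing".
#' @param elite_fraction fraction of initial branches in the elite set
#'   (default 0.12).
#' @param quantum node expansions per branch per round-robin turn.
#' @return an `lm_solution` with `objective`, `bound` and `gap`.
#' @export
branch_and_bound <- function(grouped, budget_s = 120, objective_form = NULL,
                             elite_fraction = 0.12, quantum = 1000L) {
  stopifnot(budget_s > 0)
  ctx <- .solver_context(grouped, objective_form)
  deadline <- Sys.time() + budget_s

  if (length(ctx$targets) == 0L)
    return(.build_solution(ctx, list(), 0, solver = "bnb", bound = 0, gap = 0))

  greedy <- construct_greedy(grouped, objective_form = ctx$form)
  incumbent <- greedy$objective
  best <- greedy
  root_bound <- as.numeric(.prim_weight(
    .min_connect_matrix(ctx, c(ctx$targets, ctx$dep))))

  # initial branches: first-center choices of the top vehicle (+ deferral)
  v1 <- ctx$vehicle_order[1L]
  root_state <- .fresh_state(ctx, v1)
  root <- list(routes = list(), state = root_state, unserved = ctx$targets,
               cost = 0, cycle_pos = 0L, skips = 0L)
  branches <- .node_children(ctx, root)
  if (length(branches) == 0L)
    stop("no vehicle can start a route to any center with demand", call. = FALSE)

  # depth evaluation: greedy incumbent and local bound per branch
  b_inc <- b_bound <- numeric(length(branches))
  for (b in seq_along(branches)) {
    nd <- branches[[b]]
    # the open state occupies vehicle-cycle slot nd$cycle_pos
    g <- .greedy_complete(ctx, nd$routes, nd$state, nd$unserved, nd$cost,
                          nd$cycle_pos + 1L)
    b_inc[b] <- if (g$ok) g$cost else Inf
    b_bound[b] <- .node_bound(ctx, nd)
    if (g$ok && g$cost < incumbent - 1e-12) {
      incumbent <- g$cost
      best <- .build_solution(ctx, g$routes, g$cost, solver = "bnb")
    }
  }

  # elite set: 12% of branches, half best incumbents, half widest uncertainty
  nb <- length(branches)
  esize <- min(nb, max(1L, ceiling(elite_fraction * nb)))
  n_best <- if (nb >= 2L) max(1L, as.integer(ceiling(esize / 2))) else 1L
  n_unc <- if (nb >= 2L) max(1L, esize - n_best) else 0L
  by_inc <- order(b_inc, seq_len(nb))
  elite <- by_inc[seq_len(min(n_best, nb))]
  rest <- setdiff(seq_len(nb), elite)
  if (n_unc > 0L && length(rest)) {
    unc <- b_inc[rest] - b_bound[rest]
    by_unc <- rest[order(-unc, rest)]
    elite <- c(elite, by_unc[seq_len(min(n_unc, length(by_unc)))])
  }
  explore_order <- c(elite, setdiff(seq_len(nb), elite))

  stacks <- lapply(explore_order, function(b) list(branches[[b]]))
  active <- rep(TRUE, length(stacks))
  timed_out <- FALSE

  while (any(active) && !timed_out) {
    for (s in which(active)) {
      n_exp <- 0L
      while (length(stacks[[s]]) && n_exp < quantum) {
        n_exp <- n_exp + 1L
        if (n_exp %% 64L == 0L && Sys.time() > deadline) { timed_out <- TRUE; break }
        node <- stacks[[s]][[length(stacks[[s]])]]
        stacks[[s]][[length(stacks[[s]])]] <- NULL
        if (.node_bound(ctx, node) >= incumbent - 1e-9) next
        if (length(node$unserved) == 0L) {
          cost <- node$cost
          routes <- node$routes
          if (length(node$state$seq) > 1L) {
            last <- node$state$seq[length(node$state$seq)]
            cost <- cost + ctx$cost[[node$state$v]][last, ctx$dep]
            routes <- c(routes, list(list(v = node$state$v,
                                          seq = c(node$state$seq, ctx$dep))))
          }
          if (cost < incumbent - 1e-12) {
            incumbent <- cost
            best <- .build_solution(ctx, routes, cost, solver = "bnb")
          }
          next
        }
        kids <- .node_children(ctx, node)
        # push in reverse so the highest-index child is expanded first
        for (k in rev(seq_along(kids)))
          stacks[[s]][[length(stacks[[s]]) + 1L]] <- kids[[k]]
      }
      if (length(stacks[[s]]) == 0L) active[s] <- FALSE
      if (timed_out || Sys.time() > deadline) { timed_out <- TRUE; break }
    }
  }

  open_bounds <- unlist(lapply(stacks[active], function(st)
    vapply(st, function(nd) .node_bound(ctx, nd), numeric(1))))
  bound <- if (length(open_bounds)) max(root_bound, min(open_bounds)) else incumbent
  bound <- min(bound, incumbent)
  best$bound <- bound
  best$gap <- incumbent - bound
  best$search <- list(n_branches = nb, elite_size = length(elite),
                      n_best = min(n_best, nb), n_uncertainty = length(elite) -
                        min(n_best, nb), completed = !timed_out)
  best
}

# ---------------------------------------------------------------------------

# assemble an lm_solution from internal index-based routes
.build_solution <- function(ctx, routes, cost, solver, bound = NA_real_,
                            gap = NA_real_) {
  inst <- ctx$inst
  out_routes <- list()
  deliveries <- data.frame(route = integer(), center = character(),
                           cold_volume = numeric(), dry_volume = numeric())
  for (r in seq_along(routes)) {
    rt <- routes[[r]]
    seqc <- rt$seq
    depart <- numeric(length(seqc))
    for (k in seq_along(seqc)[-1]) {
      depart[k] <- depart[k - 1L] + ctx$h[[rt$v]][seqc[k - 1L], seqc[k]] +
        if (seqc[k] == ctx$dep) 0 else ctx$W
    }
    served <- seqc[seqc != ctx$dep]
    out_routes[[r]] <- list(
      vehicle = inst$vehicles$name[rt$v],
      sequence = inst$centers$name[seqc],
      depart = depart,
      duration = depart[length(depart)])
    if (length(served))
      deliveries <- rbind(deliveries, data.frame(
        route = r, center = inst$centers$name[served],
        cold_volume = ctx$D_r[served], dry_volume = ctx$D_d[served]))
  }
  structure(list(routes = out_routes, deliveries = deliveries,
                 objective = cost, bound = bound, gap = gap,
                 solver = solver, objective_form = ctx$form,
                 status = "feasible"),
            class = "lm_solution")
}

#' @export
print.lm_solution <- function(x, ...) {
  cat(sprintf("%s solution (%s objective): %d route(s), objective %.6g",
              x$solver, x$objective_form, length(x$routes), x$objective))
  if (!is.na(x$bound))
    cat(sprintf(", bound %.6g, gap %.3g", x$bound, x$gap))
  cat("\n")
  for (r in seq_along(x$routes))
    cat(sprintf("  route %d [%s]: %s (%.2f h)\n", r, x$routes[[r]]$vehicle,
                paste(x$routes[[r]]$sequence, collapse = " -> "),
                x$routes[[r]]$duration))
  invisible(x)
}
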