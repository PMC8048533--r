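#' Build the exact mixed-integer program for a grouped instance
#'
#' Creates the routing MIP over the two product classes (cold/dry): binary
#' arc indicators `y[i,j,v]` over all center pairs (diagonal included, fixed
#' to zero) and vehicles, continuous flows `x[i,j,v,p]` in liters for
#' p in \{cold, dry\}, and continuous departure times `t[i,v]` in hours. The
#' constraint families are: flow conservation meeting each center's demand;
#' initial cold/dry loads within vehicle capacities; big-M time sequencing
#' along chosen arcs (with the drop-off time); guaranteed return to the depot
#' within the maximum route duration; vehicles and flows may only leave the
#' depot if the vehicle departs it (big-M linking); degree balance at every
#' center; no self-arcs; arcs restricted to available roads; flow only on
#' chosen arcs; and at most one depot departure per vehicle (one route per
#' vehicle -- additional routes are the construction heuristic's extension
#' and are not part of the exact model). The objective minimizes the sum of
#' [arc_cost()] over chosen arcs.
#'
#' Big-M values: `M_time = l + W + max h`, `M_count = |C|^2`,
#' `M_flow,p` = total demand volume of class p.
#'
#' @param grouped an `lm_grouped`.
#' @param objective_form "printed" or "increasing"; defaults to the
#'   instance's configured form.
#' @param big_M_scale multiplier (>= 1) applied to all big-M constants; the
#'   documented values are already sufficient, so scaling them up must not
#'   change the optimum (useful for checking M sufficiency).
#' @return an object of class `lm_mip` with the sparse constraint triplets,
#'   bounds, objective, `n_variables` and `n_constraints`.
#' @export
build_mip <- function(grouped, objective_form = NULL, big_M_scale = 1) {
  ctx <- .solver_context(grouped, objective_form)
  nC <- ctx$nC; nV <- ctx$nV; dep <- ctx$dep
  if (nV < 1L) stop("cannot build model: no vehicles", call. = FALSE)
  D <- cbind(cold = ctx$D_r, dry = ctx$D_d)
  ny <- nC * nC * nV
  nx <- 2L * ny
  nt <- nC * nV
  ncol <- ny + nx + nt

  y_id <- function(i, j, v) (v - 1L) * nC * nC + (j - 1L) * nC + i
  x_id <- function(i, j, v, p) ny + (p - 1L) * ny + y_id(i, j, v)
  t_id <- function(i, v) ny + nx + (v - 1L) * nC + i

  l <- ctx$l; W <- ctx$W
  stopifnot(big_M_scale >= 1)
  M_time <- (l + W + max(vapply(ctx$h, max, numeric(1)))) * big_M_scale
  M_count <- nC^2 * big_M_scale
  M_flow <- colSums(D) * big_M_scale

  obj <- numeric(ncol)
  for (v in seq_len(nV)) obj[y_id(1L, 1L, v) : y_id(nC, nC, v)] <- ctx$cost[[v]]

  lb <- numeric(ncol)
  ub <- rep(Inf, ncol)
  # y: binary, off the diagonal, on available arcs only (Eqs 10, 11, 13)
  for (v in seq_len(nV)) {
    ubm <- ctx$avail
    diag(ubm) <- 0
    ub[y_id(1L, 1L, v) : y_id(nC, nC, v)] <- ubm
  }
  # x: nonnegative, bounded by the total class volume (Eq 14)
  for (p in 1:2) ub[(ny + (p - 1L) * ny + 1L):(ny + p * ny)] <- M_flow[p]
  # t: within the route duration (Eq 15 and the return constraints)
  ub[(ny + nx + 1L):ncol] <- l
  integrality <- c(rep(1L, ny), rep(0L, nx + nt))

  ai <- aj <- ax <- numeric(0)
  cl <- cu <- numeric(0)
  row <- 0L
  add_row <- function(cols, coefs, lo, hi) {
    row <<- row + 1L
    ai <<- c(ai, rep(row, length(cols)))
    aj <<- c(aj, cols)
    ax <<- c(ax, coefs)
    cl <<- c(cl, lo)
    cu <<- c(cu, hi)
  }

  # (2) net inflow meets demand at every center but the depot (the depot is
  # the source; applying the equality there would contradict loading)
  for (p in 1:2) for (j in seq_len(nC)) {
    if (j == dep) next
    cols <- coefs <- numeric(0)
    for (v in seq_len(nV)) for (i in seq_len(nC)) {
      if (i == j) next
      cols <- c(cols, x_id(i, j, v, p), x_id(j, i, v, p))
      coefs <- c(coefs, 1, -1)
    }
    add_row(cols, coefs, D[j, p], D[j, p])
  }

  # (3)/(4) initial load out of the depot within compartment capacity
  caps <- cbind(ctx$cap_r, ctx$cap_d)
  for (p in 1:2) for (v in seq_len(nV)) {
    js <- setdiff(seq_len(nC), dep)
    add_row(vapply(js, function(j) x_id(dep, j, v, p), numeric(1)),
            rep(1, length(js)), -Inf, caps[v, p])
  }

  # (5) time sequencing: t_jv >= t_iv + h + W when arc (i,j) is used
  for (v in seq_len(nV)) for (j in seq_len(nC)) {
    if (j == dep) next
    for (i in seq_len(nC)) {
      if (i == j) next
      add_row(c(t_id(j, v), t_id(i, v), y_id(i, j, v)),
              c(1, -1, -M_time),
              ctx$h[[v]][i, j] + W - M_time, Inf)
    }
  }

  # (6) the vehicle can always return to the depot within l
  for (v in seq_len(nV)) for (i in seq_len(nC)) for (j in seq_len(nC)) {
    cols <- c(t_id(i, v), y_id(i, dep, v), y_id(i, j, v))
    coefs <- c(1, -W, ctx$h[[v]][i, j] + ctx$h[[v]][j, dep])
    add_row(cols, coefs, -Inf, l - W)
  }

  # (7) arcs only if the vehicle departs the depot
  for (v in seq_len(nV)) {
    cols <- coefs <- numeric(0)
    for (j in seq_len(nC)) for (i in seq_len(nC)) {
      cols <- c(cols, y_id(i, j, v))
      coefs <- c(coefs, if (i == dep) 1 - M_count else 1)
    }
    add_row(cols, coefs, -Inf, 0)
  }

  # (8) flow only if flow departs the depot
  for (p in 1:2) for (v in seq_len(nV)) {
    cols <- coefs <- numeric(0)
    for (j in seq_len(nC)) for (i in seq_len(nC)) {
      cols <- c(cols, x_id(i, j, v, p))
      coefs <- c(coefs, if (i == dep) 1 - M_flow[p] else 1)
    }
    add_row(cols, coefs, -Inf, 0)
  }

  # (9) degree balance: a vehicle entering a center leaves it
  for (v in seq_len(nV)) for (j in seq_len(nC)) {
    cols <- coefs <- numeric(0)
    for (i in seq_len(nC)) {
      if (i == j) next
      cols <- c(cols, y_id(i, j, v), y_id(j, i, v))
      coefs <- c(coefs, 1, -1)
    }
    add_row(cols, coefs, 0, 0)
  }

  # (12) flow forces the arc indicator
  for (p in 1:2) for (v in seq_len(nV)) for (j in seq_len(nC)) for (i in seq_len(nC)) {
    add_row(c(y_id(i, j, v), x_id(i, j, v, p)), c(M_flow[p], -1), 0, Inf)
  }

  # one route per vehicle: at most one depot departure
  for (v in seq_len(nV)) {
    js <- setdiff(seq_len(nC), dep)
    add_row(vapply(js, function(j) y_id(dep, j, v), numeric(1)),
            rep(1, length(js)), -Inf, 1)
  }

  structure(list(
    obj = obj, lb = lb, ub = ub, integrality = integrality,
    ai = ai, aj = aj, ax = ax, cl = cl, cu = cu,
    n_variables = ncol, n_constraints = row,
    ny = ny, nx = nx, nt = nt, nC = nC, nV = nV, dep = dep,
    grouped = grouped, objective_form = ctx$form,
    M = c(time = M_time, count = M_count, flow_cold = M_flow[[1]],
          flow_dry = M_flow[[2]])
  ), class = "lm_mip")
}

#' @export
print.lm_mip <- function(x, ...) {
  cat(sprintf("routing MIP: %d variables (%d binary), %d constraints, %s objective\n",
              x$n_variables, x$ny, x$n_constraints, x$objective_form))
  invisible(x)
}

# locate the python interpreter for the branch-and-cut backend
.backend_python <- function() {
  py <- getOption("lastmile.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("the MIP backend needs a Python interpreter with scipy on the PATH ",
         "(set options(lastmile.python = ...) to point at one)", call. = FALSE)
  py
}

.json_num <- function(x) {
  x[x == Inf] <- 1e30
  x[x == -Inf] <- -1e30
  x
}

# run one or more serialized models through the HiGHS backend in one process
.milp_backend <- function(models, time_limit, mip_gap) {
  payload <- list(models = lapply(models, function(m) list(
    ncol = m$n_variables,
    obj = m$obj, lb = .json_num(m$lb), ub = .json_num(m$ub),
    integrality = m$integrality,
    ai = m$ai - 1, aj = m$aj - 1, ax = m$ax,
    cl = .json_num(m$cl), cu = .json_num(m$cu),
    time_limit = time_limit, mip_gap = mip_gap)))
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  helper <- system.file("python", "milp_solve.py", package = "lastmile")
  status <- system2(.backend_python(), c(shQuote(helper), shQuote(infile),
                                         shQuote(outfile)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("MIP backend failed: ", paste(status, collapse = "\n"), call. = FALSE)
  jsonlite::read_json(outfile, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)$solutions
}

#' Solve a routing MIP with the external branch-and-cut backend
#'
#' Serializes the model and solves it with the HiGHS branch-and-cut solver
#' through `scipy.optimize.milp` in a Python subprocess (see
#' `SystemRequirements`). Deterministic for a fixed model and settings.
#'
#' @param model an `lm_mip` from [build_mip()], or a list of them (solved in
#'   one backend call).
#' @param time_limit seconds allowed for the solver.
#' @param mip_gap relative optimality gap for claiming optimality.
#' @return an `lm_mip_solution` (or a list of them): `status` ("optimal",
#'   "limit", "infeasible", ...), `objective`, `bound`, `gap`, and the `y`,
#'   `x`, `t` variable arrays.
#' @export
solve_mip <- function(model, time_limit = 120, mip_gap = 1e-6) {
  single <- inherits(model, "lm_mip")
  models <- if (single) list(model) else model
  stopifnot(all(vapply(models, inherits, logical(1), "lm_mip")))
  raw <- .milp_backend(models, time_limit, mip_gap)
  sols <- lapply(seq_along(models), function(k)
    .mip_solution(models[[k]], raw[[k]]))
  if (single) sols[[1]] else sols
}

.mip_solution <- function(model, r) {
  status <- r$status
  sol <- list(status = status, objective = NA_real_, bound = NA_real_,
              gap = NA_real_, y = NULL, x = NULL, t = NULL,
              objective_form = model$objective_form)
  if (status %in% c("optimal", "limit") && !is.null(r$x) && length(r$x)) {
    nC <- model$nC; nV <- model$nV
    xv <- as.numeric(r$x)
    sol$objective <- as.numeric(r$objective)
    sol$bound <- if (!is.null(r$bound)) as.numeric(r$bound) else NA_real_
    sol$gap <- if (!is.na(sol$bound)) sol$objective - sol$bound else NA_real_
    sol$y <- array(round(xv[seq_len(model$ny)]), dim = c(nC, nC, nV))
    sol$x <- array(xv[model$ny + seq_len(model$nx)], dim = c(nC, nC, nV, 2L))
    sol$t <- matrix(xv[model$ny + model$nx + seq_len(model$nt)], nC, nV)
  } else if (status == "infeasible") {
    sol$diagnostic <- .infeasibility_diagnostic(model$grouped)
  }
  class(sol) <- "lm_mip_solution"
  sol
}

# name the structural family most likely responsible for infeasibility
.infeasibility_diagnostic <- function(grouped) {
  inst <- grouped$instance
  ctx <- .solver_context(grouped)
  targets <- ctx$targets
  reach <- .reachable_from(ctx$avail, ctx$dep)
  if (any(!reach[targets]))
    return(sprintf("availability: center(s) %s unreachable over available roads",
                   paste(inst$centers$name[targets[!reach[targets]]], collapse = ", ")))
  too_big <- targets[ctx$D_r[targets] > max(ctx$cap_r) + 1e-9 |
                     ctx$D_d[targets] > max(ctx$cap_d) + 1e-9]
  if (length(too_big))
    return(sprintf("capacity: demand volume at %s exceeds every vehicle's compartment",
                   paste(inst$centers$name[too_big], collapse = ", ")))
  no_time <- targets[vapply(targets, function(j) all(vapply(seq_len(ctx$nV),
    function(v) ctx$h[[v]][ctx$dep, j] + ctx$W + ctx$h[[v]][j, ctx$dep] >
      ctx$l + 1e-9, logical(1))), logical(1))]
  if (length(no_time))
    return(sprintf("time: round trip to %s exceeds the route duration limit for every vehicle",
                   paste(inst$centers$name[no_time], collapse = ", ")))
  "unidentified (all single-center checks pass; combined capacity/time likely)"
}

#' Extract ordered routes from a MIP solution
#'
#' Follows the chosen arcs of each vehicle from the depot into an ordered
#' route, takes departure times from the time variables, and attributes the
#' delivered cold/dry volume at each center to the vehicle carrying it (net
#' flow in minus flow out). Chosen arcs forming a cycle that does not pass
#' through the depot indicate a model defect and raise an integrity error.
#'
#' @param mipsol an `lm_mip_solution` with feasible status.
#' @param grouped the `lm_grouped` the model was built from.
#' @return an `lm_solution`.
#' @export
extract_routes <- function(mipsol, grouped) {
  if (!mipsol$status %in% c("optimal", "limit") || is.null(mipsol$y))
    stop("cannot extract routes from a solution with status ", mipsol$status,
         call. = FALSE)
  ctx <- .solver_context(grouped, mipsol$objective_form)
  nC <- ctx$nC; dep <- ctx$dep
  routes <- list()
  deliveries <- data.frame(route = integer(), center = character(),
                           cold_volume = numeric(), dry_volume = numeric())
  for (v in seq_len(dim(mipsol$y)[3])) {
    yv <- mipsol$y[, , v]
    used <- which(yv > 0.5, arr.ind = TRUE)
    if (nrow(used) == 0L) next
    succ <- rep(NA_integer_, nC)
    succ[used[, 1]] <- used[, 2]
    seqv <- dep
    cur <- succ[dep]
    if (is.na(cur))
      stop("solution-integrity error: vehicle ", ctx$inst$vehicles$name[v],
           " uses arcs but never departs the depot", call. = FALSE)
    n_steps <- 0L
    while (!is.na(cur)) {
      seqv <- c(seqv, cur)
      if (cur == dep) break
      cur <- succ[cur]
      n_steps <- n_steps + 1L
      if (n_steps > nC)
        stop("solution-integrity error: arc-following did not return to the depot",
             call. = FALSE)
    }
    if (seqv[length(seqv)] != dep)
      stop("solution-integrity error: route of vehicle ",
           ctx$inst$vehicles$name[v], " does not close at the depot", call. = FALSE)
    if (nrow(used) != length(seqv) - 1L)
      stop("solution-integrity error: chosen arcs contain a cycle not through the depot",
           call. = FALSE)
    r <- length(routes) + 1L
    visited <- seqv[-c(1L, length(seqv))]
    # the model's time variables only constrain the ordering (they can carry
    # big-M slack); report the tight schedule: drive plus drop-off per stop
    depart <- numeric(length(seqv))
    for (k in seq_along(seqv)[-1])
      depart[k] <- depart[k - 1L] + ctx$h[[v]][seqv[k - 1L], seqv[k]] +
        if (seqv[k] == dep) 0 else ctx$W
    routes[[r]] <- list(
      vehicle = ctx$inst$vehicles$name[v],
      sequence = ctx$inst$centers$name[seqv],
      depart = depart,
      duration = depart[length(depart)])
    if (length(visited)) {
      cold <- vapply(visited, function(j)
        sum(mipsol$x[, j, v, 1]) - sum(mipsol$x[j, , v, 1]), numeric(1))
      dry <- vapply(visited, function(j)
        sum(mipsol$x[, j, v, 2]) - sum(mipsol$x[j, , v, 2]), numeric(1))
      deliveries <- rbind(deliveries, data.frame(
        route = r, center = ctx$inst$centers$name[visited],
        cold_volume = cold, dry_volume = dry))
    }
  }
  structure(list(routes = routes, deliveries = deliveries,
                 objective = mipsol$objective, bound = mipsol$bound,
                 gap = mipsol$gap, solver = "mip",
                 objective_form = mipsol$objective_form,
                 status = mipsol$status),
            class = "lm_solution")
}
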