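#' Normalize the user objective weight
#'
#' The user enters a single transit-time weight on a 0..10 scale; the two
#' objective weights always total 10, so the penalty weight is implied.
#' Entering 10 optimizes transit time only; entering 0 optimizes the road and
#' vehicle penalties only.
#'
#' @param raw numeric in \[0, 10\].
#' @return named numeric vector `c(W_t, W_p)` with `W_t = raw/10`,
#'   `W_p = 1 - W_t`.
#' @examples
#' normalize_weights(6)  # W_t = 0.6, W_p = 0.4
#' @export
normalize_weights <- function(raw) {
  if (!is.numeric(raw) || length(raw) != 1L || is.na(raw) || raw < 0 || raw > 10)
    stop("transit-time weight must be a single number in [0, 10]", call. = FALSE)
  c(W_t = raw / 10, W_p = 1 - raw / 10)
}

#' Scale demand back to the available supply
#'
#' When the monthly demand for a product exceeds the supply available at the
#' depot, the demand is scaled back proportionally until it matches the
#' supply; products with sufficient supply are left untouched. Scaled demands
#' are rounded down to whole units and the remaining units are redistributed
#' by largest fractional remainder (ties broken by center order), so the
#' scaled column sum never exceeds the supply.
#'
#' @param demand |C| x |P| matrix of units.
#' @param products product data.frame (needs `available_supply`).
#' @return list with `demand` (the scaled matrix) and `scaled` (logical per
#'   product: was the column reduced).
#' @export
scale_demand <- function(demand, products) {
  demand <- as.matrix(demand)
  supply <- products$available_supply
  scaled <- logical(ncol(demand))
  out <- demand
  for (p in seq_len(ncol(demand))) {
    tot <- sum(demand[, p])
    if (tot <= supply[p] || tot == 0) next
    scaled[p] <- TRUE
    target <- floor(supply[p] + 1e-9)
    raw <- demand[, p] * supply[p] / tot
    base <- floor(raw + 1e-9)
    rem <- target - sum(base)
    if (rem > 0) {
      # largest remainder; ties by center order (stable sort)
      ord <- order(-(raw - base), seq_along(raw))
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    out[, p] <- base
  }
  list(demand = out, scaled = scaled)
}

#' Group products into cold and dry classes
#'
#' Reduces the product dimension of the optimization to two classes --
#' refrigerated (cold) and nonrefrigerated (dry) -- by converting the scaled
#' per-product demand into per-center volumes
#' \eqn{D_i^r = \sum_{p\ cold} d_{ip} k_p} and
#' \eqn{D_i^d = \sum_{p\ dry} d_{ip} k_p} (liters). The per-product detail is
#' retained for post-hoc disaggregation of the deliveries.
#'
#' @param inst an `lm_instance`.
#' @param double_mean passed to [compute_means()].
#' @return an object of class `lm_grouped`: the instance plus `cold_demand`,
#'   `dry_demand` (named per-center volumes), `scaled_demand` (units),
#'   `means`, `W_t`, `W_p`, and `scaling_notes`.
#' @export
group_products <- function(inst, double_mean = TRUE) {
  sc <- scale_demand(inst$demand, inst$products)
  vol <- .demand_volumes(sc$demand, inst$products)
  names(vol$cold) <- names(vol$dry) <- inst$centers$name
  notes <- if (any(sc$scaled)) sprintf(
    "demand for %s scaled back to available supply; consider a repeat delivery when more stock arrives",
    paste(inst$products$name[sc$scaled], collapse = ", ")) else character()
  structure(list(
    instance = inst,
    scaled_demand = sc$demand,
    cold_demand = vol$cold,
    dry_demand = vol$dry,
    means = compute_means(inst, double_mean = double_mean),
    W_t = inst$parameters$W_t,
    W_p = inst$parameters$W_p,
    scaling_notes = notes
  ), class = "lm_grouped")
}

#' @export
print.lm_grouped <- function(x, ...) {
  cat(sprintf("grouped instance: %d centers, total cold volume %.2f L, dry %.2f L\n",
              nrow(x$instance$centers), sum(x$cold_demand), sum(x$dry_demand)))
  invisible(x)
}

#' Storage-capacity warnings for a grouped instance
#'
#' One warning per (center, storage class) whose scaled demand volume exceeds
#' the center's storage capacity. These never block solving: the assumption
#' is that storage will be available when the delivery arrives.
#'
#' @param grouped an `lm_grouped`.
#' @return character vector of warnings (possibly empty).
#' @export
storage_warnings <- function(grouped) {
  inst <- grouped$instance
  out <- character()
  for (i in seq_len(nrow(inst$centers))) {
    if (grouped$cold_demand[i] > inst$centers$cold_capacity[i] + 1e-9)
      out <- c(out, sprintf(
        "cold demand volume at %s (%.2f L) exceeds cold storage capacity (%.2f L)",
        inst$centers$name[i], grouped$cold_demand[i], inst$centers$cold_capacity[i]))
    if (grouped$dry_demand[i] > inst$centers$dry_capacity[i] + 1e-9)
      out <- c(out, sprintf(
        "dry demand volume at %s (%.2f L) exceeds dry storage capacity (%.2f L)",
        inst$centers$name[i], grouped$dry_demand[i], inst$centers$dry_capacity[i]))
  }
  out
}
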