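#' Arc cost of the routing objective
#'
#' The objective of the routing model is a weighted sum, over the chosen arcs,
#' of a transit-time term and a penalty term, each passed through an
#' exponential of the value scaled by its mean so the two are comparable:
#' in the `printed` form the cost of arc (i, j) with vehicle v is
#' \deqn{W_t e^{-h_{ijv}/\mu_h} + W_p (e^{-\gamma_{ij}/\mu_\gamma} + e^{-\beta_v/\mu_\beta})}
#' and the `increasing` form flips the signs of the exponents so the cost
#' grows with transit time and penalties. Both forms are strictly positive.
#' The `printed` form is the model's definition and reproduces the published
#' objective magnitudes; the `increasing` form is offered because the printed
#' exponentials decrease in time and penalty, which runs against the stated
#' minimization goals (see the methods vignette).
#'
#' @param h transit time(s), hours.
#' @param gamma road penalty(ies).
#' @param beta vehicle penalty(ies).
#' @param W_t,W_p objective weights (sum to 1).
#' @param means an `lm_means` object (see [compute_means()]).
#' @param objective_form "printed" (default) or "increasing".
#' @return numeric cost, vectorized over `h`/`gamma`/`beta`.
#' @export
arc_cost <- function(h, gamma, beta, W_t, W_p, means,
                     objective_form = c("printed", "increasing")) {
  objective_form <- match.arg(objective_form)
  s <- if (objective_form == "printed") -1 else 1
  W_t * exp(s * .scaled(h, means$mu_h)) +
    W_p * (exp(s * .scaled(gamma, means$mu_gamma)) +
           exp(s * .scaled(beta, means$mu_beta)))
}

# value/mean, treating a degenerate zero mean (all values zero) as "at the
# mean" so the exponential terms stay finite
.scaled <- function(x, mu) {
  if (mu > 0) x / mu else x * 0 + 1
}

#' Arc-cost matrix for one vehicle
#'
#' @param grouped an `lm_grouped`.
#' @param v vehicle index or name.
#' @param objective_form "printed" or "increasing"; defaults to the
#'   instance's configured form.
#' @return |C| x |C| matrix of arc costs (diagonal included; self-arcs are
#'   excluded from routing by the feasibility rules, not here).
#' @export
arc_cost_matrix <- function(grouped, v, objective_form = NULL) {
  inst <- grouped$instance
  objective_form <- objective_form %||% inst$parameters$objective_form
  vv <- if (is.character(v)) .vehicle_index(inst, v) else v
  h <- transit_matrix(inst, vv)
  arc_cost(h, inst$roads$gamma, inst$vehicles$penalty[vv],
           grouped$W_t, grouped$W_p, grouped$means, objective_form)
}
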