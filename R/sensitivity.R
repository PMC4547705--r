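# Relative-sensitivity statistic of the fitted cost.
#
# For parameter i with estimate theta_i and optimized cost L(theta_hat),
#   S(theta_i) = ( |L(theta_hat + D e_i) - L(theta_hat)| / |L(theta_hat)| )
#              / ( |D| / theta_i ),
# evaluated on a symmetric grid D in [-0.1 theta_i, 0.1 theta_i].  The
# perturbation is applied to the single coordinate exactly as written --
# perturbing one splitting probability deliberately leaves rho
# unnormalized (the likelihood tolerates this); an optional flag
# renormalizes rho instead, for comparison.

# Internal: sensitivity profile of an arbitrary scalar cost.
sensitivity_profile <- function(cost, theta_hat, i, deltas_rel) {
  L0 <- cost(theta_hat)
  if (!is.finite(L0) || L0 == 0)
    stop("undefined sensitivity: the cost at the estimate is ",
         if (is.finite(L0)) "zero" else "not finite")
  deltas_rel <- deltas_rel[abs(deltas_rel) > 1e-15]
  vapply(deltas_rel, function(rel) {
    th <- theta_hat
    th[i] <- th[i] + rel * theta_hat[i]
    L <- cost(th)
    (abs(L - L0) / abs(L0)) / abs(rel)
  }, numeric(1))
}

#' Relative sensitivity of the likelihood to each parameter
#'
#' Quantifies how strongly each fate parameter affects the optimized
#' frequency likelihood: the relative change of the cost per relative
#' change of the parameter, profiled over perturbations of up to +-10% of
#' the estimate.  Parameters with large profiles are the ones the
#' experimental design actually pins down.
#'
#' @param params_hat fitted `mgw_parameters` (or an `mgw_fit`).
#' @param data an `mgw_dataset`.
#' @param initial initial count vector over the type space.
#' @param topology an `mgw_topology`.
#' @param parameters indices (1..10, order of [as_theta()]) or names of
#'   the parameters to profile; default all 10.
#' @param n_grid number of symmetric grid points spanning
#'   `[-0.1, 0.1] * theta_i` (default 21); the center point `D = 0`,
#'   where the statistic is 0/0, is excluded.
#' @param renormalize_rho if `TRUE`, a perturbed splitting probability is
#'   followed by rescaling rho back onto the simplex (default `FALSE`:
#'   the raw one-coordinate perturbation is used).
#' @param scope,jitter as in [negative_log_likelihood()].
#' @return an `mgw_sensitivity` data.frame with columns `parameter`,
#'   `delta_rel`, `delta`, `S`; `summary()` gives the per-parameter
#'   maximum profile, largest first.
#' @export
relative_sensitivity <- function(params_hat, data, initial,
                                 topology = network_topology(),
                                 parameters = 1:10, n_grid = 21,
                                 renormalize_rho = FALSE,
                                 scope = "global", jitter = 1e-10) {
  if (inherits(params_hat, "mgw_fit")) params_hat <- params_hat$parameters
  theta_hat <- as_theta(params_hat)
  if (is.character(parameters)) parameters <- match(parameters, theta_names())
  stopifnot(all(parameters %in% 1:10))
  prep <- prep_likelihood(data, params_hat, topology, initial, scope)
  cost <- function(th) {
    if (renormalize_rho) {
      s <- sum(th[8:10])
      if (s > 0) th[8:10] <- th[8:10] / s
    }
    params <- theta_to_parameters(th, params_hat, validate = FALSE)
    as.numeric(nll_prepared(params, prep, topology, jitter,
                            allow_unnormalized_rho = !renormalize_rho))
  }
  grid <- seq(-0.1, 0.1, length.out = n_grid)
  grid <- grid[abs(grid) > 1e-15]
  out <- do.call(rbind, lapply(parameters, function(i) {
    data.frame(parameter = theta_names()[i],
               delta_rel = grid,
               delta = grid * theta_hat[i],
               S = sensitivity_profile(cost, theta_hat, i, grid),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("mgw_sensitivity", "data.frame")
  out
}

#' @export
summary.mgw_sensitivity <- function(object, ...) {
  s <- tapply(object$S, object$parameter, max)
  out <- data.frame(parameter = names(s), max_S = as.numeric(s),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$max_S), ]
  rownames(out) <- NULL
  out
}
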