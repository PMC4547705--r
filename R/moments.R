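#' Moment operators of the branching step
#'
#' Precomputes the matrices driving the exact first- and second-order
#' moment recursions of the per-type counts.  Because every fate outcome
#' delivers all its copies to a single target type, the per-cell second
#' moment `E[o o^T]` is diagonal, and with `Q[j, t] = sum_k p_k size_k^2`
#' over outcomes of type `j` targeting `t` the recursion is
#' \deqn{\mu(n+1) = M^T \mu(n)}
#' \deqn{\Sigma(n+1) = M^T (\Sigma(n) - diag(\mu(n))) M + diag(Q^T \mu(n)),}
#' which equals the textbook multi-type Galton-Watson form
#' `M^T Sigma M + sum_j mu_j V_j` with `V_j` the per-type offspring
#' covariance.
#'
#' @param params an `mgw_parameters`.
#' @param topology an `mgw_topology`.
#' @param allow_unnormalized_rho tolerate `sum(rho) != 1` (sensitivity
#'   perturbations); the recursion is applied to the raw entries.
#' @return list with `M`, `Q`, `type_space`.
#' @export
moment_operators <- function(params, topology, allow_unnormalized_rho = FALSE) {
  ts <- build_type_space(topology, params$p)
  ft <- fate_table(params, topology, ts, allow_unnormalized_rho)
  mm <- moment_matrices(ft, nrow(ts), attr(ts, "labels"))
  list(M = mm$M, Q = mm$Q, type_space = ts)
}

#' Moment state of the population
#'
#' @param mean expected count vector over the type space (cells).
#' @param cov count covariance matrix (cells^2); defaults to 0 (a
#'   deterministic state).
#' @param n step index.
#' @return an object of class `mgw_moment_state`.
#' @export
moment_state <- function(mean, cov = NULL, n = 0L) {
  mean <- as.numeric(mean)
  if (is.null(cov)) cov <- matrix(0, length(mean), length(mean))
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  structure(list(mean = mean, cov = cov, n = as.integer(n)),
            class = "mgw_moment_state")
}

#' Advance population moments by one step
#'
#' @param state an `mgw_moment_state` at step `n`.
#' @param ops moment operators from [moment_operators()].
#' @return the `mgw_moment_state` at step `n + 1`; the covariance is
#'   symmetrized by construction.
#' @export
step_moments <- function(state, ops) {
  M <- ops$M
  if (length(state$mean) != nrow(M)) stop("dimension mismatch")
  mu <- state$mean
  mu1 <- drop(crossprod(M, mu))
  A <- state$cov
  diag(A) <- diag(A) - mu
  S1 <- crossprod(M, A %*% M)
  diag(S1) <- diag(S1) + drop(crossprod(ops$Q, mu))
  S1 <- (S1 + t(S1)) / 2
  moment_state(mu1, S1, state$n + 1L)
}

#' Propagate moments over several steps
#'
#' Runs the exact moment recursion from a (deterministic) initial
#' population: element `k + 1` of the result is the moment state after `k`
#' steps.  A deterministic initial state has zero covariance.
#'
#' @param initial numeric count vector over the type space, or an
#'   `mgw_moment_state` (whose covariance is then propagated too).
#' @param params an `mgw_parameters`.
#' @param topology an `mgw_topology`.
#' @param n_steps number of steps (>= 0).
#' @param allow_unnormalized_rho see [moment_operators()].
#' @return list of `mgw_moment_state` for n = 0..n_steps.
#' @examples
#' topo <- network_topology()
#' th <- default_parameters()
#' ts <- build_type_space(topo, th$p)
#' z0 <- numeric(nrow(ts)); z0[type_index(ts, "DR", 0)] <- 100
#' ms <- propagate_moments(z0, th, topo, 2)
#' ms[[2]]$mean[type_index(ts, "DR", 0)]   # 100 * delta_0 = 43
#' @export
propagate_moments <- function(initial, params, topology, n_steps,
                              allow_unnormalized_rho = FALSE) {
  ops <- moment_operators(params, topology, allow_unnormalized_rho)
  st <- if (inherits(initial, "mgw_moment_state")) initial
        else moment_state(initial, n = 0L)
  if (length(st$mean) != nrow(ops$M))
    stop("initial state has length ", length(st$mean),
         " but the type space has ", nrow(ops$M), " types")
  out <- vector("list", n_steps + 1L)
  out[[1L]] <- st
  for (k in seq_len(n_steps)) out[[k + 1L]] <- step_moments(out[[k]], ops)
  out
}

#' Delta-method moments of relative cell frequencies
#'
#' Converts count moments into moments of the per-scope relative
#' frequencies `f = Z / sum(Z)` used for inference: the mean is
#' `pi = mu_s / sum(mu_s)` and the covariance is the delta-method form
#' `Omega = J Sigma_s J^T` with `J = (I - pi 1^T) / sum(mu_s)`, the
#' Jacobian of the normalization at the mean.  Rows/columns of `Omega`
#' sum to zero (frequencies sum to a constant), so `Omega` is singular:
#' likelihood consumers drop one category.
#'
#' @param state an `mgw_moment_state`.
#' @param scope integer indices (into the type space) of the categories
#'   over which frequencies are formed, e.g. all measured organ types.
#' @param labels optional category labels.
#' @return object of class `mgw_freq_moments`: list with `pi`, `omega`,
#'   `scope`, `labels`, `total_mean`, `n`.
#' @export
frequency_moments <- function(state, scope, labels = NULL) {
  mu <- state$mean[scope]
  tot <- sum(mu)
  if (!is.finite(tot) || tot <= 0)
    stop("undefined frequencies: total mean in scope is not positive")
  pi <- mu / tot
  S <- state$cov[scope, scope, drop = FALSE]
  k <- length(scope)
  J <- (diag(k) - tcrossprod(pi, rep(1, k))) / tot
  Om <- J %*% S %*% t(J)
  Om <- (Om + t(Om)) / 2
  if (!is.null(labels)) { names(pi) <- labels; dimnames(Om) <- list(labels, labels) }
  structure(list(pi = pi, omega = Om, scope = scope, labels = labels,
                 total_mean = tot, n = state$n),
            class = "mgw_freq_moments")
}

#' Structurally reachable types at each step
#'
#' Boolean forward propagation of the support of the mean matrix, using a
#' generic strictly-positive parameterization with the same structure
#' (migrating set, cap rule, stage count) as `params`.  Used to fix the
#' likelihood's category sets independently of the parameter values being
#' fitted: a type is in scope at step `n` only if some lineage starting
#' from the initial support can occupy it after `n` steps.
#'
#' @param initial numeric count vector (its support is what matters).
#' @param params an `mgw_parameters` (structure donor).
#' @param topology an `mgw_topology`.
#' @param n_steps number of steps.
#' @return logical matrix `(n_steps + 1) x D`; row `k` flags the types
#'   reachable at step `k - 1`.
#' @export
reachable_types <- function(initial, params, topology, n_steps) {
  generic <- model_parameters(
    gamma = rep(0.3, length(params$gamma)),
    delta = rep(0.3, length(params$delta)),
    m = 0.2,
    rho = stats::setNames(rep(1 / max(1, length(params$rho)),
                              length(params$rho)), names(params$rho)),
    dt_hours = params$dt_hours, p = params$p,
    migrating_generations = params$migrating_generations,
    generation_cap_rule = params$generation_cap_rule,
    divide_at_cap = params$divide_at_cap,
    proliferate_in_transit = params$proliferate_in_transit,
    validate = FALSE)
  S <- offspring_mean_matrix(generic, topology) > 0
  D <- nrow(S)
  out <- matrix(FALSE, n_steps + 1L, D)
  out[1L, ] <- as.numeric(initial) > 0
  for (k in seq_len(n_steps))
    out[k + 1L, ] <- drop(crossprod(S, out[k, ])) > 0
  colnames(out) <- rownames(S)
  out
}

#' Tidy export of a moment trajectory
#'
#' @param states list of `mgw_moment_state` (from [propagate_moments()]).
#' @param type_space the matching `mgw_type_space`.
#' @param dt_hours step duration, for the redundant `time_hours` column.
#' @param t0_hours wall-clock time of step 0 (default 72).
#' @return data.frame with columns `n`, `time_hours`, `compartment`,
#'   `generation`, `mean`, `variance`.
#' @export
moments_to_df <- function(states, type_space, dt_hours = 4, t0_hours = 72) {
  do.call(rbind, lapply(states, function(st) {
    data.frame(n = st$n,
               time_hours = t0_hours + dt_hours * st$n,
               compartment = type_space$compartment,
               generation = type_space$generation,
               mean = st$mean,
               variance = diag(st$cov),
               stringsAsFactors = FALSE)
  }))
}
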