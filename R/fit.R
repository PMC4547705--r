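# Constrained maximum-likelihood estimation of the 10 fate parameters.
#
# The optimizer works on the reduced 9-vector (delta0, gamma0, delta1,
# gamma1, delta2, gamma2, m, rho_spl, rho_il); rho_mes is eliminated via
# the simplex.  Box bounds keep every coordinate in (0, 1); the
# per-generation simplex constraints gamma_i + delta_i + m_i <= 1 and
# rho_spl + rho_il <= 1 are enforced by projection plus a smooth
# quadratic penalty.

reduced_names <- function() theta_names()[1:9]

reduced_to_theta <- function(th) {
  stats::setNames(c(th, 1 - th[8] - th[9]), theta_names())
}

# Internal: project a reduced vector into the feasible region (scaled
# shrink towards the origin) and return the constraint overshoot.
project_reduced <- function(th, template, margin = 1e-4) {
  mig <- template$migrating_generations
  m_for <- function(i)  # generations with probability index i (cap rule)
    if (any(c(i, if (i == 2) 3:(template$p - 1)) %in% mig)) th[7] else 0
  sums <- vapply(0:2, function(i) th[2 * i + 1] + th[2 * i + 2] + m_for(i),
                 numeric(1))
  r <- max(sums)
  over <- max(0, r - (1 - margin))
  if (over > 0) {
    sc <- (1 - margin) / r
    th[1:7] <- th[1:7] * sc
  }
  s <- th[8] + th[9]
  over_rho <- max(0, s - (1 - margin))
  if (over_rho > 0) th[8:9] <- th[8:9] * (1 - margin) / s
  list(th = th, overshoot = over + over_rho)
}

# Internal: draw one feasible start from the constrained-uniform law
# (uniform on the box, rejected until all simplex constraints hold with a
# working margin).
draw_start <- function(template, margin = 0.02) {
  for (try in 1:10000) {
    th <- stats::runif(9)
    pr <- project_reduced(th, template, margin)
    if (pr$overshoot == 0) return(th)
  }
  stop("could not draw a feasible starting point")
}

#' Fit the branching-network model by maximum likelihood
#'
#' Minimizes the normal-approximation negative log-likelihood of the
#' observed cell frequencies over the 10 fate parameters, subject to the
#' box \[0, 1\], the splitting simplex `sum(rho) = 1`, and
#' `gamma_i + delta_i + m_i <= 1`.  A multi-start strategy (default 20
#' constrained-uniform starts, fixed seed) guards against local minima:
#' every start gets a coarse L-BFGS-B pass and the best is polished to
#' convergence.  Standard errors come from the observed Fisher
#' information ([fisher_standard_errors()]).
#'
#' @param data an `mgw_dataset` (at least two time steps with nonzero
#'   counts).
#' @param initial numeric initial count vector; `NULL` (default) builds it
#'   from the step-0 animals via [initial_state_from_data()].
#' @param topology an `mgw_topology`.
#' @param template structural template (`p`, migrating set, `dt`, cap
#'   behaviour) for the fitted parameters.
#' @param scope frequency scope, `"global"` or `"per_organ"`.
#' @param starts number of optimizer starts (default 20).
#' @param seed seed for the start draws (default 1).
#' @param compute_se compute Fisher standard errors (default `TRUE`).
#' @param control list of optimizer knobs: `coarse_maxit` (60),
#'   `polish_maxit` (500), `factr_coarse` (1e10), `factr_polish` (1e7),
#'   `penalty` (1e6), `jitter` (1e-10).
#' @return an object of class `mgw_fit`: fitted `parameters`, the named
#'   `theta` vector, `se`, `nll`, per-start `convergence` diagnostics,
#'   identifiability flags.
#' @export
fit_mle <- function(data, initial = NULL, topology = network_topology(),
                    template = default_parameters(), scope = "global",
                    starts = 20L, seed = 1L, compute_se = TRUE,
                    control = list()) {
  ctrl <- utils::modifyList(
    list(coarse_maxit = 30L, polish_maxit = 500L,
         factr_coarse = 1e11, factr_polish = 1e7,
         penalty = 1e6, jitter = 1e-10), control)
  steps_nz <- unique(data$n[data$count > 0])
  if (length(steps_nz) < 2L)
    stop("degenerate dataset: need nonzero counts at >= 2 time steps")
  if (is.null(initial))
    initial <- initial_state_from_data(data, template, topology)
  prep <- prep_likelihood(data, template, topology, initial, scope)

  objective <- function(th) {
    pr <- project_reduced(th, template)
    params <- theta_to_parameters(reduced_to_theta(pr$th), template,
                                  validate = FALSE)
    val <- nll_prepared(params, prep, topology, ctrl$jitter)
    if (!is.finite(val)) return(1e12)
    as.numeric(val) + ctrl$penalty * pr$overshoot^2
  }

  set.seed(seed)
  start_mat <- t(vapply(seq_len(starts), function(s) draw_start(template),
                        numeric(9)))
  lo <- rep(1e-4, 9); hi <- rep(1 - 1e-4, 9)
  runs <- lapply(seq_len(starts), function(s) {
    o <- tryCatch(
      stats::optim(start_mat[s, ], objective, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = ctrl$coarse_maxit,
                                  factr = ctrl$factr_coarse)),
      error = function(e) NULL)
    if (is.null(o)) list(par = start_mat[s, ], value = Inf,
                         convergence = 99L, counts = c(NA, NA))
    else o
  })
  vals <- vapply(runs, function(o) o$value, numeric(1))
  if (!any(is.finite(vals)))
    stop("no optimizer start converged; per-start values: ",
         paste(signif(vals, 4), collapse = ", "))
  best <- which.min(vals)
  polish <- stats::optim(runs[[best]]$par, objective, method = "L-BFGS-B",
                         lower = lo, upper = hi,
                         control = list(maxit = ctrl$polish_maxit,
                                        factr = ctrl$factr_polish))
  th_hat <- project_reduced(polish$par, template)$th
  theta <- reduced_to_theta(th_hat)
  params_hat <- theta_to_parameters(theta, template)
  nll_hat <- nll_prepared(params_hat, prep, topology, ctrl$jitter)

  sink_counts <- sum(data$count[data$organ %in% topology$sinks])
  rho_identifiable <- sink_counts > 0
  if (!rho_identifiable) {
    warning("no cells were ever observed in the sink organs; the ",
            "splitting probabilities rho are not identifiable and are ",
            "reported as NA")
    theta[c("rho_spl", "rho_il", "rho_mes")] <- NA_real_
  }
  diag_df <- data.frame(
    start = seq_len(starts),
    value = vals,
    convergence = vapply(runs, function(o) as.integer(o$convergence),
                         integer(1)))
  fit <- structure(
    list(parameters = params_hat, theta = theta,
         se = stats::setNames(rep(NA_real_, 10), theta_names()),
         nll = as.numeric(nll_hat),
         nll_singular = isTRUE(attr(nll_hat, "singular")),
         convergence = diag_df, n_starts = starts, seed = seed,
         scope = scope, initial = initial,
         rho_identifiable = rho_identifiable,
         se_singular = NA),
    class = "mgw_fit")
  if (compute_se) {
    se <- fisher_standard_errors(params_hat, data, initial, topology,
                                 scope = scope, jitter = ctrl$jitter)
    fit$se <- se$se
    fit$se_singular <- se$singular
    fit$se_boundary <- se$boundary
    if (!rho_identifiable)
      fit$se[c("rho_spl", "rho_il", "rho_mes")] <- NA_real_
  }
  fit
}

#' @export
print.mgw_fit <- function(x, ...) {
  cat("Branching-network maximum-likelihood fit\n")
  cat(sprintf("  NLL = %.6g  (%d starts, scope = %s)\n",
              x$nll, x$n_starts, x$scope))
  tab <- data.frame(estimate = x$theta, std_error = x$se)
  print(round(tab, 4))
  if (!x$rho_identifiable)
    cat("  note: rho not identifiable (no sink observations)\n")
  if (isTRUE(x$se_singular))
    cat("  note: Fisher information singular; SEs from pseudo-inverse\n")
  invisible(x)
}

# Internal: standard errors from the inverse numerical Hessian of a
# scalar cost at a point; pseudo-inverse fallback when the Hessian is not
# positive definite.
hessian_se <- function(fn, theta, ndeps = 1e-4) {
  H <- stats::optimHess(theta, fn,
                        control = list(ndeps = rep(ndeps, length(theta))))
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) NULL)
  singular <- FALSE
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    V <- MASS::ginv(H)
    singular <- TRUE
  }
  list(se = sqrt(pmax(diag(V), 0)), cov = V, singular = singular)
}

#' Fisher-information standard errors
#'
#' Computes the observed Fisher information as the numerical Hessian of
#' the negative log-likelihood at the estimate, on the reduced
#' 9-parameter space (`rho_mes` eliminated via the simplex), and maps the
#' inverse back to all 10 reported parameters; the `rho_mes` standard
#' error follows from the delta method on `rho_mes = 1 - rho_spl -
#' rho_il`.  A non-positive-definite Hessian falls back to the
#' Moore-Penrose pseudo-inverse with a singularity flag; estimates within
#' 1e-3 of a box/simplex boundary are flagged, since the quadratic
#' approximation is then unreliable.
#'
#' @param params_hat fitted `mgw_parameters` (or an `mgw_fit`).
#' @param data,initial,topology,scope,jitter as in
#'   [negative_log_likelihood()].
#' @return list with `se` (named 10-vector), `cov` (9 x 9), `singular`,
#'   `boundary`.
#' @export
fisher_standard_errors <- function(params_hat, data, initial,
                                   topology = network_topology(),
                                   scope = "global", jitter = 1e-10) {
  if (inherits(params_hat, "mgw_fit")) params_hat <- params_hat$parameters
  prep <- prep_likelihood(data, params_hat, topology, initial, scope)
  fn <- function(th) {
    params <- theta_to_parameters(reduced_to_theta(th), params_hat,
                                  validate = FALSE)
    v <- nll_prepared(params, prep, topology, jitter)
    if (!is.finite(v)) 1e12 else as.numeric(v)
  }
  th <- as_theta(params_hat)[1:9]
  boundary <- any(th < 1e-3) || any(th > 1 - 1e-3) ||
    project_reduced(th, params_hat, margin = 1e-3)$overshoot > 0
  hs <- hessian_se(fn, th)
  se <- stats::setNames(c(hs$se, NA_real_), theta_names())
  # delta method: var(rho_mes) = var(r_spl) + var(r_il) + 2 cov
  v_mes <- hs$cov[8, 8] + hs$cov[9, 9] + 2 * hs$cov[8, 9]
  se["rho_mes"] <- sqrt(max(v_mes, 0))
  list(se = se, cov = hs$cov, singular = hs$singular, boundary = boundary)
}
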