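#' Model parameters of the branching network
#'
#' Bundles the probabilistic fate parameters of the per-step multi-type
#' Galton-Watson law.  In each step a cell of generation `i` divides with
#' probability `gamma[i]` (producing two cells of generation `i + 1`),
#' stays quiescent with probability `delta[i]`, migrates out of the source
#' with probability `m` (only for generations in
#' `migrating_generations`), and dies with the residual probability.
#' Division and quiescence probabilities are generation-specific for
#' generations 0, 1 and 2; generations beyond 2 inherit the generation-2
#' values (`generation_cap_rule = "inherit_gen2"`).  Cells leaving the
#' transfer compartment split onto the sinks with multinomial
#' probabilities `rho` (summing to 1).
#'
#' @param gamma per-generation division probabilities; length 3
#'   (generations 0, 1, 2 — later generations inherit the last entry) or
#'   length `p + 1` with `generation_cap_rule = "explicit"`.
#' @param delta per-generation quiescence probabilities, same shape as
#'   `gamma`.
#' @param m migration probability per step out of the source, shared by
#'   all migrating generations.
#' @param rho named splitting probabilities `c(spl=, il=, mes=)` (or
#'   matching the topology's `rho_keys`), summing to 1.
#' @param dt_hours duration of one step (hours); a structural constant.
#' @param p maximum trackable generation (>= 2).
#' @param migrating_generations generations subject to migration; must
#'   exclude 0 and `p`.  Default `1:3`.
#' @param generation_cap_rule `"inherit_gen2"` (default) or `"explicit"`.
#' @param divide_at_cap if `TRUE` (default) divisions from generation `p`
#'   produce two generation-`p` cells (the dye-saturated pool keeps
#'   growing); if `FALSE` generation-`p` cells do not divide.
#' @param proliferate_in_transit if `TRUE`, cells in transfer stages are
#'   subject to the same division/quiescence/death law while advancing;
#'   default `FALSE` (pure delay line).
#' @param validate stop on invalid parameters (default `TRUE`).
#' @return an object of class `mgw_parameters`.
#' @seealso [validate_parameters()], [default_parameters()]
#' @export
model_parameters <- function(gamma, delta, m, rho,
                             dt_hours = 4, p = 7,
                             migrating_generations = 1:3,
                             generation_cap_rule = c("inherit_gen2", "explicit"),
                             divide_at_cap = TRUE,
                             proliferate_in_transit = FALSE,
                             validate = TRUE) {
  generation_cap_rule <- match.arg(generation_cap_rule)
  obj <- structure(
    list(gamma = as.numeric(gamma),
         delta = as.numeric(delta),
         m = as.numeric(m),
         rho = unlist(rho),
         dt_hours = as.numeric(dt_hours),
         p = as.integer(p),
         migrating_generations = sort(unique(as.integer(migrating_generations))),
         generation_cap_rule = generation_cap_rule,
         divide_at_cap = isTRUE(divide_at_cap),
         proliferate_in_transit = isTRUE(proliferate_in_transit)),
    class = "mgw_parameters")
  if (validate) {
    bad <- validate_parameters(obj)
    if (length(bad)) stop("invalid model parameters:\n  - ",
                          paste(bad, collapse = "\n  - "))
  }
  obj
}

#' Reference parameter values for CD4+ T cell priming
#'
#' Division, quiescence, migration and splitting probabilities per 4-hour
#' step characteristic of antigen-specific CD4+ T cell clonal expansion
#' and dissemination after nasal immunization (draining cervical lymph
#' node source; spleen, iliac and mesenteric lymph node sinks).  These
#' values also parameterize the package's canonical synthetic fixture.
#'
#' @param ... overrides passed on to [model_parameters()].
#' @return an `mgw_parameters` object.
#' @examples
#' th <- default_parameters()
#' 1 - th$delta[1] - th$gamma[1]   # generation-0 death probability, > 0.5
#' @export
default_parameters <- function(...) {
  args <- list(
    gamma = c(0.06, 0.29, 0.24),
    delta = c(0.43, 0.31, 0.23),
    m = 0.14,
    rho = c(spl = 0.95, il = 0.01, mes = 0.04))
  over <- list(...)
  args[names(over)] <- over
  do.call(model_parameters, args)
}

#' Validate model parameters
#'
#' Pure check: returns a character vector describing every violated
#' invariant (empty when the parameters are valid).  Checked: probability
#' ranges; the per-generation simplex constraints
#' `gamma_i + delta_i + m_i <= 1` in the source (with `m_i = m` for
#' migrating generations, 0 otherwise) and `gamma_i + delta_i <= 1` in the
#' sinks; `sum(rho) == 1` within 1e-12; the migrating set excluding
#' generations 0 and `p`; shapes of `gamma`/`delta` under the cap rule.
#'
#' @param params an `mgw_parameters` object.
#' @param tol tolerance for the simplex constraints (default 1e-9).
#' @return character vector of violations, `character(0)` when valid.
#' @export
validate_parameters <- function(params, tol = 1e-9) {
  v <- character(0)
  g <- params$gamma; d <- params$delta
  p <- params$p
  if (is.na(p) || p < 2L) v <- c(v, sprintf("p = %s but must be an integer >= 2", p))
  want_len <- if (params$generation_cap_rule == "inherit_gen2") 3L else p + 1L
  if (length(g) != want_len || length(d) != want_len)
    v <- c(v, sprintf("gamma and delta must have length %d under cap rule '%s'",
                      want_len, params$generation_cap_rule))
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
    v <- c(v, "gamma entries must lie in [0, 1]")
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
    v <- c(v, "delta entries must lie in [0, 1]")
  if (length(params$m) != 1L || !is.finite(params$m) ||
      params$m < 0 || params$m > 1)
    v <- c(v, "m must be a single probability in [0, 1]")
  if (length(params$rho)) {
    if (any(!is.finite(params$rho)) || any(params$rho < 0) || any(params$rho > 1))
      v <- c(v, "rho entries must lie in [0, 1]")
    if (abs(sum(params$rho) - 1) > 1e-12)
      v <- c(v, sprintf("splitting probabilities sum != 1 (sum = %.15g)",
                        sum(params$rho)))
  }
  mg <- params$migrating_generations
  if (length(mg) && (any(mg < 1) || any(mg >= p)))
    v <- c(v, sprintf("migrating generations must lie in 1..%d (generations 0 and p do not migrate)", p - 1L))
  if (length(v)) return(v)  # shape errors make the per-generation checks moot
  gens <- 0:p
  gi <- g[pmin(gens, length(g) - 1L) + 1L]
  di <- d[pmin(gens, length(d) - 1L) + 1L]
  mi <- ifelse(gens %in% mg, params$m, 0)
  for (i in which(gi + di + mi > 1 + tol))
    v <- c(v, sprintf("gamma_%d + delta_%d + m_%d = %.6g > 1",
                      gens[i], gens[i], gens[i], gi[i] + di[i] + mi[i]))
  if (params$dt_hours <= 0) v <- c(v, "dt_hours must be positive")
  v
}

#' Per-generation fate probability under the cap rule
#'
#' @param params an `mgw_parameters`.
#' @param which `"gamma"` or `"delta"`.
#' @param i generation(s), 0-based; generations beyond the last explicit
#'   entry inherit it.
#' @return numeric vector of probabilities.
#' @export
generation_prob <- function(params, which = c("gamma", "delta"), i) {
  which <- match.arg(which)
  x <- params[[which]]
  x[pmin(i, length(x) - 1L) + 1L]
}

#' @export
print.mgw_parameters <- function(x, ...) {
  cat("Branching-network fate parameters (per", x$dt_hours, "h step)\n")
  gens <- seq_along(x$gamma) - 1L
  cat("  generation     :", paste(gens, collapse = "  "),
      if (x$generation_cap_rule == "inherit_gen2") " (i > 2 inherit i = 2)", "\n")
  cat("  division gamma :", paste(format(x$gamma), collapse = "  "), "\n")
  cat("  quiescence delta:", paste(format(x$delta), collapse = "  "), "\n")
  cat("  migration m    :", x$m, " (generations ",
      paste(x$migrating_generations, collapse = ","), ")\n", sep = "")
  cat("  splitting rho  :", paste(names(x$rho), format(x$rho), collapse = "  "), "\n")
  cat("  max generation p:", x$p, "\n")
  invisible(x)
}

# Full 10-parameter vector in the canonical reporting order.
theta_names <- function() c("delta0", "gamma0", "delta1", "gamma1",
                            "delta2", "gamma2", "m",
                            "rho_spl", "rho_il", "rho_mes")

#' Flatten parameters to the canonical 10-vector
#' @param params an `mgw_parameters` with the default cap rule.
#' @return named numeric vector `(delta0, gamma0, delta1, gamma1, delta2,
#'   gamma2, m, rho_spl, rho_il, rho_mes)`.
#' @export
as_theta <- function(params) {
  stopifnot(inherits(params, "mgw_parameters"),
            params$generation_cap_rule == "inherit_gen2")
  stats::setNames(
    c(params$delta[1], params$gamma[1], params$delta[2], params$gamma[2],
      params$delta[3], params$gamma[3], params$m,
      params$rho[["spl"]], params$rho[["il"]], params$rho[["mes"]]),
    theta_names())
}

#' Rebuild parameters from the canonical 10-vector
#' @param theta numeric vector in the order of [as_theta()].
#' @param template an `mgw_parameters` supplying the structural constants
#'   (p, dt, migrating set, cap behaviour).
#' @param validate stop on invalid values (default `TRUE`).
#' @return an `mgw_parameters` object.
#' @export
theta_to_parameters <- function(theta, template = default_parameters(),
                                validate = TRUE) {
  stopifnot(length(theta) == 10L)
  model_parameters(
    gamma = theta[c(2, 4, 6)],
    delta = theta[c(1, 3, 5)],
    m = theta[7],
    rho = c(spl = unname(theta[8]), il = unname(theta[9]), mes = unname(theta[10])),
    dt_hours = template$dt_hours, p = template$p,
    migrating_generations = template$migrating_generations,
    generation_cap_rule = "inherit_gen2",
    divide_at_cap = template$divide_at_cap,
    proliferate_in_transit = template$proliferate_in_transit,
    validate = validate)
}
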