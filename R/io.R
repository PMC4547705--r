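# Readers/writers.  Counts travel as long-format CSV with the exact
# header `animal_id,time_hours,n,organ,generation,count`; model
# configurations and fit results travel as JSON (YAML configurations are
# also read).  All numeric output is written at full precision so
# round-trips are lossless.

counts_schema <- c("animal_id", "time_hours", "n", "organ", "generation", "count")

#' Read an observed-counts CSV
#'
#' @param path CSV file with header exactly
#'   `animal_id,time_hours,n,organ,generation,count`.
#' @param topology an `mgw_topology` fixing the organ labels.
#' @param p maximum generation (default 7).
#' @param dt_hours,t0_hours time convention; `time_hours` must equal
#'   `t0_hours + dt_hours * n` in every row.
#' @return an `mgw_dataset`.
#' @export
read_counts_csv <- function(path, topology = network_topology(), p = 7,
                            dt_hours = 4, t0_hours = 72) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), counts_schema))
    stop("bad header: expected '", paste(counts_schema, collapse = ","),
         "' but found '", paste(names(df), collapse = ","), "'")
  observed_dataset(df, topology, p, dt_hours, t0_hours)
}

#' Write an observed-counts CSV
#' @param data an `mgw_dataset` (or conforming data.frame).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_counts_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data)[counts_schema], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a model configuration
#'
#' JSON (always written) or YAML (also read) with keys `dt_hours`, `p`,
#' `transit_hours` or `n_transfer_stages`, `migrating_generations`,
#' `divide_at_cap`, `proliferate_in_transit`, and
#' `parameters: {gamma, delta, m, rho: {spl, il, mes}}`.  Written JSON
#' round-trips bit-exactly (write -> read -> write gives identical bytes).
#'
#' @param params an `mgw_parameters`.
#' @param topology an `mgw_topology`.
#' @param path output path (`.json`).
#' @return the path, invisibly.
#' @export
write_model_config <- function(params, topology, path) {
  cfg <- list(
    dt_hours = params$dt_hours,
    p = params$p,
    n_transfer_stages = length(topology$transfer_stages),
    migrating_generations = params$migrating_generations,
    generation_cap_rule = params$generation_cap_rule,
    divide_at_cap = params$divide_at_cap,
    proliferate_in_transit = params$proliferate_in_transit,
    parameters = list(gamma = params$gamma, delta = params$delta,
                      m = params$m, rho = as.list(params$rho)))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @param default_rho_keys sink label -> rho key map for the rebuilt
#'   topology.
#' @return for `read_model_config()`: list with `params` and `topology`.
#' @export
read_model_config <- function(path,
                              default_rho_keys = c(SPL = "spl", ILN = "il",
                                                   MLN = "mes")) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  dt <- cfg$dt_hours %||% 4
  topo <- if (!is.null(cfg$n_transfer_stages))
    network_topology(n_transfer_stages = cfg$n_transfer_stages,
                     dt_hours = dt, sinks = default_rho_keys)
  else network_topology(transit_hours = cfg$transit_hours %||% 12,
                        dt_hours = dt, sinks = default_rho_keys)
  pp <- cfg$parameters
  params <- model_parameters(
    gamma = pp$gamma, delta = pp$delta, m = pp$m,
    rho = unlist(pp$rho),
    dt_hours = dt, p = cfg$p %||% 7,
    migrating_generations = cfg$migrating_generations %||% 1:3,
    generation_cap_rule = cfg$generation_cap_rule %||% "inherit_gen2",
    divide_at_cap = cfg$divide_at_cap %||% TRUE,
    proliferate_in_transit = cfg$proliferate_in_transit %||% FALSE)
  list(params = params, topology = topo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fit result to JSON
#'
#' All floats are written at full precision and the key order is stable,
#' so write -> read preserves every value bit-exactly (including the
#' singular-information and identifiability flags).
#'
#' @param fit an `mgw_fit`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "mgw_fit"))
  payload <- list(
    theta = as.list(fit$theta),
    se = as.list(fit$se),
    nll = fit$nll,
    nll_singular = fit$nll_singular,
    n_starts = fit$n_starts,
    seed = fit$seed,
    scope = fit$scope,
    rho_identifiable = fit$rho_identifiable,
    se_singular = fit$se_singular,
    se_boundary = fit$se_boundary %||% NA,
    convergence = fit$convergence,
    initial = fit$initial)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null", always_decimal = FALSE)
  invisible(path)
}

#' @rdname write_fit_json
#' @return for `read_fit_json()`: an `mgw_fit`-like list with the stored
#'   estimates, standard errors, NLL and diagnostics.
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # nulls (serialized NAs) must not be dropped from named vectors
  to_num <- function(l) {
    if (!is.list(l)) return(unlist(l))
    vapply(l, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  }
  fit <- list(
    theta = to_num(x$theta),
    se = to_num(x$se),
    nll = x$nll,
    nll_singular = isTRUE(x$nll_singular),
    n_starts = x$n_starts,
    seed = x$seed,
    scope = x$scope,
    rho_identifiable = isTRUE(x$rho_identifiable),
    se_singular = x$se_singular,
    se_boundary = x$se_boundary,
    convergence = x$convergence,
    initial = as.numeric(x$initial))
  # NA slips through JSON as null -> NA already handled by unlist
  class(fit) <- "mgw_fit"
  fit
}
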