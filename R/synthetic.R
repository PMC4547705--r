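#' Sacrifice-design specification for synthetic datasets
#'
#' Describes the in vivo study design the generator emulates: groups of
#' animals sacrificed at each measurement step (so each animal is an
#' independent stochastic realization of the same branching process), a
#' known initial population in the draining node at step 0, and the true
#' fate parameters.
#'
#' @param animals_per_step animals sacrificed at each step (default 5).
#' @param steps measurement steps, sorted ascending from 0
#'   (default `c(0, 3, 6)`, i.e. 72/84/96 h at 4 h steps).
#' @param initial_counts numeric vector of source-organ counts by
#'   generation; names are generations (unnamed vectors are taken as
#'   generations `0..length-1`).
#' @param params true `mgw_parameters` generating the data.
#' @param seed root seed; every animal derives an independent substream.
#' @param size_cv optional lognormal coefficient of variation applied to
#'   each animal's initial population size (default 0: all animals start
#'   from the identical initial state), emulating inter-individual
#'   heterogeneity beyond branching noise.
#' @return an object of class `mgw_design`.
#' @export
design_spec <- function(animals_per_step = 5L, steps = c(0L, 3L, 6L),
                        initial_counts = 5e4 * c(0.10, 0.25, 0.30, 0.25, 0.10),
                        params = default_parameters(), seed = 1L,
                        size_cv = 0) {
  steps <- sort(unique(as.integer(steps)))
  if (animals_per_step < 1L) stop("need at least one animal per step")
  if (steps[1] != 0L) stop("the design must include step 0 (the initial state)")
  if (is.null(names(initial_counts)))
    names(initial_counts) <- seq_along(initial_counts) - 1L
  gens <- as.integer(names(initial_counts))
  if (any(gens < 0) || any(gens > params$p))
    stop("initial generations must lie in 0..p")
  if (any(initial_counts < 0) || any(initial_counts != round(initial_counts)))
    stop("initial counts must be non-negative integers")
  structure(list(animals_per_step = as.integer(animals_per_step),
                 steps = steps, initial_counts = initial_counts,
                 params = params, seed = as.integer(seed),
                 size_cv = size_cv),
            class = "mgw_design")
}

#' Generate a synthetic CFSE-style dataset
#'
#' For each animal sacrificed at step `n`, simulates an independent
#' sample path of the branching network from the initial state to step
#' `n` and records the generation-resolved counts of the measured organs
#' only (source and sinks; transfer stages are hidden, as they cannot be
#' assayed in vivo).  Step-0 animals record their initial state directly.
#' The whole dataset is reproducible from the design seed.
#'
#' @param design an `mgw_design`.
#' @param topology an `mgw_topology`.
#' @param out_prefix if non-`NULL`, writes `<prefix>_counts.csv` and
#'   `<prefix>_truth.json` (generating parameters, seed, design).
#' @return an `mgw_dataset` with the generating truth attached as
#'   attribute `"truth"`.
#' @export
generate_synthetic_dataset <- function(design, topology = network_topology(),
                                       out_prefix = NULL) {
  stopifnot(inherits(design, "mgw_design"))
  params <- design$params
  ts <- build_type_space(topology, params$p)
  fates <- fate_table(params, topology, ts)
  organs <- c(topology$source, topology$sinks)
  gens <- 0:params$p
  meas_idx <- type_index(ts, rep(organs, each = length(gens)),
                         rep(gens, times = length(organs)))
  z0 <- numeric(nrow(ts))
  z0[type_index(ts, topology$source, as.integer(names(design$initial_counts)))] <-
    design$initial_counts
  rows <- list()
  animal <- 0L
  for (n in design$steps) {
    for (k in seq_len(design$animals_per_step)) {
      animal <- animal + 1L
      set.seed(path_seed(design$seed, animal))
      z <- z0
      if (design$size_cv > 0) {
        sdl <- sqrt(log(1 + design$size_cv^2))
        z <- round(z0 * stats::rlnorm(1, -sdl^2 / 2, sdl))
      }
      if (n > 0) for (s in seq_len(n)) z <- simulate_step(z, params, topology, fates)
      rows[[animal]] <- data.frame(
        animal_id = sprintf("n%d_a%d", n, k),
        time_hours = 72 + params$dt_hours * n,
        n = n,
        organ = rep(organs, each = length(gens)),
        generation = rep(gens, times = length(organs)),
        count = z[meas_idx],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  data <- observed_dataset(df, topology, params$p,
                           dt_hours = params$dt_hours)
  truth <- list(theta = as.list(as_theta(params)),
                seed = design$seed,
                design = list(animals_per_step = design$animals_per_step,
                              steps = design$steps,
                              initial_counts = as.list(design$initial_counts),
                              size_cv = design$size_cv,
                              p = params$p,
                              dt_hours = params$dt_hours,
                              migrating_generations = params$migrating_generations))
  attr(data, "truth") <- truth
  if (!is.null(out_prefix)) {
    write_counts_csv(data, paste0(out_prefix, "_counts.csv"))
    jsonlite::write_json(truth, paste0(out_prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  data
}

#' Canonical synthetic fixture
#'
#' The package's reference dataset for validation and parameter-recovery
#' experiments: true parameters from [default_parameters()], an initial
#' draining-node population of 5x10^4 cells composed
#' (0.10, 0.25, 0.30, 0.25, 0.10) over generations 0-4 (mass in the first
#' five generations, as 72 h CFSE histograms show), 5 animals per step at
#' steps \{0, 3, 6\}, seed 20150824.
#'
#' @param seed root seed (default 20150824).
#' @param ... overrides forwarded to [design_spec()].
#' @return list with `data` (an `mgw_dataset`), `truth`, and `design`.
#' @export
default_fixture <- function(seed = 20150824, ...) {
  design <- design_spec(seed = seed, ...)
  data <- generate_synthetic_dataset(design)
  list(data = data, truth = attr(data, "truth"), design = design)
}
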