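#' Advance a population one step by exact stochastic simulation
#'
#' For every type with a positive count `Z`, draws one multinomial with
#' `Z` trials over the type's fate outcomes (division, quiescence,
#' migration/advance, sink entry, death) and delivers the implied
#' offspring; this is equivalent in law to independent per-cell fates but
#' costs O(types) per step.  Types with zero count consume no random
#' numbers.
#'
#' @param state integer count vector over the type space.
#' @param params an `mgw_parameters`.
#' @param topology an `mgw_topology`.
#' @param fates optional precomputed fate table (internal reuse).
#' @return integer count vector at the next step.
#' @export
simulate_step <- function(state, params, topology, fates = NULL) {
  if (is.null(fates)) {
    ts <- build_type_space(topology, params$p)
    if (length(state) != nrow(ts))
      stop("state has length ", length(state), " but the type space has ",
           nrow(ts), " types")
    fates <- fate_table(params, topology, ts)
  }
  nxt <- numeric(length(state))
  for (j in which(state > 0)) {
    f <- fates[[j]]
    if (!length(f$prob)) next                      # certain death
    draw <- stats::rmultinom(1L, state[j], c(f$prob, max(0, 1 - sum(f$prob))))
    for (k in seq_along(f$prob)) {
      t <- f$target[k]
      nxt[t] <- nxt[t] + draw[k] * f$size[k]
    }
  }
  nxt
}

# Internal: deterministic per-path seed derived from a root seed.
# Arithmetic (not sequential RNG draws) so path i's trajectory does not
# depend on how many paths are requested.
path_seed <- function(seed, path) {
  as.integer((as.double(seed) + 48271 * as.double(path)) %% 2147483647)
}

#' Simulate an ensemble of independent sample paths
#'
#' Each path restarts the Mersenne-Twister stream from a seed derived
#' arithmetically from `(seed, path)`, so path `i` is identical whether 10
#' or 10,000 paths are requested and the ensemble is reproducible.
#'
#' @param initial integer count vector over the type space at step 0.
#' @param params an `mgw_parameters`.
#' @param topology an `mgw_topology`.
#' @param n_steps number of steps to simulate.
#' @param n_paths number of independent trajectories (>= 1).
#' @param seed root integer seed.
#' @return an `mgw_ensemble`: a 3-d array `[path, step, type]` (steps
#'   indexed 0..n_steps) with the type space attached as an attribute.
#' @seealso [simulate_ensemble()] for a vectorized equivalent-in-law
#'   sampler sharing one stream across paths.
#' @export
simulate_paths <- function(initial, params, topology, n_steps, n_paths,
                           seed = 1L) {
  stopifnot(n_paths >= 1, n_steps >= 0)
  ts <- build_type_space(topology, params$p)
  if (length(initial) != nrow(ts))
    stop("initial state does not match the type space")
  if (any(initial < 0) || any(initial != round(initial)))
    stop("initial counts must be non-negative integers")
  fates <- fate_table(params, topology, ts)
  arr <- array(0, dim = c(n_paths, n_steps + 1L, nrow(ts)),
               dimnames = list(NULL, 0:n_steps, attr(ts, "labels")))
  for (i in seq_len(n_paths)) {
    set.seed(path_seed(seed, i))
    z <- as.numeric(initial)
    arr[i, 1L, ] <- z
    for (s in seq_len(n_steps)) {
      z <- simulate_step(z, params, topology, fates)
      arr[i, s + 1L, ] <- z
    }
  }
  structure(arr, type_space = ts, class = c("mgw_ensemble", "array"))
}

#' Vectorized ensemble simulation (one shared stream)
#'
#' Equivalent in law to [simulate_paths()] but draws each type's
#' multinomial jointly across all paths via sequential conditional
#' binomials, which is orders of magnitude faster for large ensembles.
#' Individual paths are not invariant to `n_paths` here; use
#' [simulate_paths()] when per-path reproducibility matters.
#'
#' @inheritParams simulate_paths
#' @return an `mgw_ensemble` array `[path, step, type]`.
#' @export
simulate_ensemble <- function(initial, params, topology, n_steps, n_paths,
                              seed = 1L) {
  stopifnot(n_paths >= 1, n_steps >= 0)
  ts <- build_type_space(topology, params$p)
  if (length(initial) != nrow(ts))
    stop("initial state does not match the type space")
  fates <- fate_table(params, topology, ts)
  D <- nrow(ts)
  set.seed(seed)
  arr <- array(0, dim = c(n_paths, n_steps + 1L, D),
               dimnames = list(NULL, 0:n_steps, attr(ts, "labels")))
  Z <- matrix(as.numeric(initial), n_paths, D, byrow = TRUE)
  arr[, 1L, ] <- Z
  for (s in seq_len(n_steps)) {
    nxt <- matrix(0, n_paths, D)
    for (j in seq_len(D)) {
      zj <- Z[, j]
      if (!any(zj > 0)) next
      f <- fates[[j]]
      if (!length(f$prob)) next
      rem <- zj; pleft <- 1
      for (k in seq_along(f$prob)) {
        q <- min(1, f$prob[k] / pleft)
        x <- stats::rbinom(n_paths, rem, q)
        nxt[, f$target[k]] <- nxt[, f$target[k]] + x * f$size[k]
        rem <- rem - x
        pleft <- pleft - f$prob[k]
        if (pleft <= 0) break
      }
    }
    Z <- nxt
    arr[, s + 1L, ] <- Z
  }
  structure(arr, type_space = ts, class = c("mgw_ensemble", "array"))
}

#' Long-format view of an ensemble
#'
#' @param x an `mgw_ensemble`.
#' @param ... unused.
#' @param drop_zero drop rows with zero count (default `TRUE`).
#' @return data.frame with columns `path`, `n`, `compartment`,
#'   `generation`, `count`.
#' @export
as.data.frame.mgw_ensemble <- function(x, ..., drop_zero = TRUE) {
  ts <- attr(x, "type_space")
  d <- dim(x)
  df <- data.frame(
    path = rep(seq_len(d[1]), times = d[2] * d[3]),
    n = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    compartment = rep(ts$compartment, each = d[1] * d[2]),
    generation = rep(ts$generation, each = d[1] * d[2]),
    count = as.vector(unclass(x)),
    stringsAsFactors = FALSE)
  if (drop_zero) df <- df[df$count > 0 | df$n == 0, ]
  rownames(df) <- NULL
  df[order(df$path, df$n), ]
}

#' Ensemble summary statistics per type and step
#'
#' @param object an `mgw_ensemble`.
#' @param ... unused.
#' @return data.frame with columns `n`, `compartment`, `generation`,
#'   `mean`, `variance` (across paths).
#' @export
summary.mgw_ensemble <- function(object, ...) {
  ts <- attr(object, "type_space")
  d <- dim(object)
  out <- do.call(rbind, lapply(seq_len(d[2]), function(s) {
    m <- apply(object[, s, , drop = FALSE], 3, mean)
    v <- apply(object[, s, , drop = FALSE], 3, stats::var)
    data.frame(n = s - 1L, compartment = ts$compartment,
               generation = ts$generation, mean = m, variance = v,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
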