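# Normal-approximation likelihood of per-animal relative frequencies.
#
# Each sacrificed animal contributes one frequency vector per scope
# (default: one vector across all measured organs jointly, normalized by
# the animal's total recorded cells).  The model supplies the mean
# frequencies pi(n) and the delta-method covariance Omega(n) of a single
# stochastic realization; the frequency vector is treated as Gaussian on
# the reduced space obtained by dropping the last category (Omega is
# singular because frequencies sum to 1).

# Internal: theta-independent data preparation.  Fixes, per time step and
# scope group, the category set (structurally reachable measured types)
# and the per-animal count matrix over it.
prep_likelihood <- function(data, params, topology, initial,
                            scope = c("global", "per_organ")) {
  scope <- match.arg(scope)
  ts <- build_type_space(topology, params$p)
  organs <- c(topology$source, topology$sinks)
  steps <- sort(unique(data$n))
  reach <- reachable_types(initial, params, topology, max(steps))
  data_idx <- type_index(ts, data$organ, data$generation)
  items <- list()
  dropped <- 0
  for (n in steps) {
    rows <- data$n == n
    animals <- unique(data$animal_id[rows])
    groups <- if (scope == "global") list(all = organs)
              else stats::setNames(as.list(organs), organs)
    for (g in names(groups)) {
      in_organ <- ts$compartment %in% groups[[g]]
      cats <- which(in_organ & reach[n + 1L, ])
      if (length(cats) < 2L) next
      cnt <- matrix(0, length(animals), length(cats),
                    dimnames = list(animals, attr(ts, "labels")[cats]))
      sel <- rows & (data_idx %in% cats)
      if (any(sel)) {
        ai <- match(data$animal_id[sel], animals)
        ci <- match(data_idx[sel], cats)
        for (r in seq_along(ai))
          cnt[ai[r], ci[r]] <- cnt[ai[r], ci[r]] + data$count[sel][r]
      }
      dropped <- dropped + sum(data$count[rows & in_organ[data_idx] &
                                            !(data_idx %in% cats)])
      items[[length(items) + 1L]] <-
        list(n = n, group = g, cats = cats, counts = cnt)
    }
  }
  if (dropped > 0)
    warning(dropped, " observed cells fall in structurally unreachable ",
            "categories and are excluded from the frequency scope")
  list(steps = steps, items = items, initial = as.numeric(initial),
       type_space = ts, scope = scope)
}

# Internal: one animal/scope Gaussian term on the reduced frequency space.
# Returns 0.5 * [ (f - pi)' Omega^-1 (f - pi) + log det(2 pi~ Omega) ]
# computed after dropping the last category; `jitter` scales the ridge
# added to Omega before factorization.
freq_nll_term <- function(f, pi, omega, jitter = 1e-10) {
  k <- length(pi) - 1L
  v <- (f - pi)[seq_len(k)]
  Om <- omega[seq_len(k), seq_len(k), drop = FALSE]
  scale <- mean(diag(Om))
  if (!is.finite(scale) || scale <= 0) return(list(value = NA_real_, singular = TRUE))
  eps <- jitter * scale
  R <- NULL
  for (try in 1:4) {
    R <- tryCatch(chol(Om + diag(eps, k)), error = function(e) NULL)
    if (!is.null(R)) break
    eps <- eps * 1e2
  }
  if (is.null(R)) {                        # persistent singularity
    ev <- eigen(Om, symmetric = TRUE)
    lam <- pmax(ev$values, 1e-12 * scale)
    u <- drop(crossprod(ev$vectors, v))
    return(list(value = 0.5 * (sum(u^2 / lam) + k * log(2 * base::pi) +
                                 sum(log(lam))),
                singular = TRUE))
  }
  z <- backsolve(R, v, transpose = TRUE)
  list(value = 0.5 * (sum(z^2) + k * log(2 * base::pi) +
                        2 * sum(log(diag(R)))),
       singular = eps > jitter * scale * 1.5)
}

# Internal: NLL given prepared data.  Invalid parameters act as a +Inf
# barrier so optimizers can roam.
nll_prepared <- function(params, prep, topology, jitter = 1e-10,
                         allow_unnormalized_rho = FALSE) {
  viol <- validate_parameters(params)
  if (allow_unnormalized_rho)   # raw one-coordinate rho perturbations
    viol <- viol[!grepl("splitting probabilities|rho entries", viol)]
  if (length(viol)) return(structure(Inf, violations = viol))
  ft <- tryCatch(fate_table(params, topology, prep$type_space,
                            allow_unnormalized_rho),
                 error = function(e) NULL)
  if (is.null(ft)) return(Inf)
  mm <- moment_matrices(ft, nrow(prep$type_space))
  ops <- list(M = mm$M, Q = mm$Q)
  states <- vector("list", max(prep$steps) + 1L)
  states[[1L]] <- moment_state(prep$initial)
  for (s in seq_len(max(prep$steps)))
    states[[s + 1L]] <- step_moments(states[[s]], ops)
  total <- 0; n_terms <- 0L; singular <- FALSE
  for (it in prep$items) {
    st <- states[[it$n + 1L]]
    mu_s <- st$mean[it$cats]
    tot_mu <- sum(mu_s)
    if (!is.finite(tot_mu) || tot_mu <= 0) next     # nothing predicted here
    S_s <- st$cov[it$cats, it$cats, drop = FALSE]
    if (sum(diag(S_s)) <= 1e-9 * max(1, tot_mu)) next  # deterministic scope
    fm <- frequency_moments(st, it$cats)
    k <- length(fm$pi) - 1L
    Om <- fm$omega[seq_len(k), seq_len(k), drop = FALSE]
    scale <- mean(diag(Om))
    if (!is.finite(scale) || scale <= 0) next
    eps <- jitter * scale
    R <- NULL
    for (try in 1:4) {
      R <- tryCatch(chol(Om + diag(eps, k)), error = function(e) NULL)
      if (!is.null(R)) break
      eps <- eps * 1e2
    }
    item_sing <- eps > jitter * scale * 1.5
    if (is.null(R)) {                 # persistent singularity: eigen fallback
      ev <- eigen(Om, symmetric = TRUE)
      lam <- pmax(ev$values, 1e-12 * scale)
      logdet <- sum(log(lam))
      quad <- function(v) sum(drop(crossprod(ev$vectors, v))^2 / lam)
      item_sing <- TRUE
    } else {
      logdet <- 2 * sum(log(diag(R)))
      quad <- function(v) sum(backsolve(R, v, transpose = TRUE)^2)
    }
    const <- k * log(2 * base::pi) + logdet
    tots <- rowSums(it$counts)
    for (a in which(tots > 0)) {      # skipping rule: zero-total animals
      f <- it$counts[a, ] / tots[a]
      val <- 0.5 * (quad((f - fm$pi)[seq_len(k)]) + const)
      if (!is.finite(val)) next
      total <- total + val
      n_terms <- n_terms + 1L
      singular <- singular || item_sing
    }
  }
  structure(total, n_terms = n_terms, singular = singular)
}

#' Negative log-likelihood of observed cell frequencies
#'
#' Evaluates the normal approximation of the negative log-likelihood of
#' the per-animal relative frequencies under the branching-network model:
#' the sum over animals of
#' `0.5 * [(f - pi(n))' Omega(n)^-1 (f - pi(n)) + log det(2*pi~*Omega(n))]`
#' on the reduced frequency space (last category dropped), where `pi` and
#' `Omega` are the delta-method frequency moments at the animal's step and
#' `pi~` denotes the circle constant.  Animals/scopes with zero observed
#' or predicted totals are skipped, as is any scope whose count covariance
#' is exactly zero (a deterministic initial time point carries no
#' frequency information).  Invalid parameters yield `+Inf` so the
#' function can serve directly as an optimization objective.
#'
#' @param theta an `mgw_parameters` object, or a numeric 10-vector in the
#'   order of [as_theta()] (then `template` supplies the structure).
#' @param data an `mgw_dataset`.
#' @param initial numeric count vector over the type space at step 0
#'   (see [initial_state_from_data()]).
#' @param topology an `mgw_topology`.
#' @param scope `"global"` (default; one frequency vector per animal over
#'   all measured organs, the normalizing variable being the animal's
#'   total recorded cells) or `"per_organ"`.
#' @param template structural template when `theta` is a bare vector.
#' @param jitter relative ridge added to the reduced frequency covariance
#'   before inversion (default 1e-10); persistent singularity falls back
#'   to an eigenvalue-clipped inverse and flags the result.
#' @param allow_unnormalized_rho tolerate `sum(rho) != 1` (single-
#'   coordinate sensitivity perturbations).
#' @return scalar NLL with attributes `n_terms` and `singular`.
#' @export
negative_log_likelihood <- function(theta, data, initial,
                                    topology = network_topology(),
                                    scope = c("global", "per_organ"),
                                    template = default_parameters(),
                                    jitter = 1e-10,
                                    allow_unnormalized_rho = FALSE) {
  scope <- match.arg(scope)
  params <- if (inherits(theta, "mgw_parameters")) theta
            else theta_to_parameters(theta, template, validate = FALSE)
  prep <- prep_likelihood(data, params, topology, initial, scope)
  nll_prepared(params, prep, topology, jitter, allow_unnormalized_rho)
}
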