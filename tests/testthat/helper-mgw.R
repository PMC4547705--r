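# Shared fixtures and independent oracles, all built in code.

ref_topology <- function() network_topology()          # 12 h / 4 h: 3 stages
ref_params <- function(...) default_parameters(...)    # reference estimates

# small sacrifice-design dataset for fast inference/io tests
small_dataset <- function(seed = 7, animals = 3, steps = c(0, 3, 6),
                          initial = 2e4 * c(0.10, 0.25, 0.30, 0.25, 0.10),
                          params = ref_params()) {
  design <- design_spec(animals_per_step = animals, steps = steps,
                        initial_counts = initial, params = params,
                        seed = seed)
  generate_synthetic_dataset(design, ref_topology())
}

# cheap optimizer knobs for tests that only need a rough optimum
quick_control <- list(coarse_maxit = 15L, polish_maxit = 200L,
                      factr_coarse = 1e11, factr_polish = 1e8)

# Oracle: mean offspring vector of one type by enumerating its fate law.
enumerated_mean_row <- function(compartment, generation, params, topology) {
  ts <- build_type_space(topology, params$p)
  od <- offspring_distribution(compartment, generation, params, topology)
  mu <- numeric(nrow(ts))
  alive <- !is.na(od$target_compartment)
  for (r in which(alive)) {
    t <- type_index(ts, od$target_compartment[r], od$target_generation[r])
    mu[t] <- mu[t] + od$prob[r] * od$n_offspring[r]
  }
  mu
}

# Oracle: exact distribution of a single-type Galton-Watson population
# after n steps from one cell, offspring in {0, 1, 2} with probabilities
# (1 - gamma - delta, delta, gamma).  Dynamic programming over the pgf.
gw_exact_dist <- function(n_steps, gamma, delta) {
  off <- c(1 - gamma - delta, delta, gamma)     # P(0), P(1), P(2) offspring
  dist <- c(0, 1)                               # start: exactly 1 cell
  for (s in seq_len(n_steps)) {
    zmax <- length(dist) - 1L
    new <- numeric(2L * zmax + 1L)
    conv <- 1                                   # offspring-sum pmf for z = 0
    for (z in 0:zmax) {
      if (dist[z + 1L] > 0)
        new[seq_along(conv)] <- new[seq_along(conv)] + dist[z + 1L] * conv
      conv <- convolve_pmf(conv, off)
    }
    dist <- new
  }
  dist                                          # dist[k + 1] = P(Z_n = k)
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# comparable view of a counts table: schema columns only, no carried
# attributes (generated datasets also carry their truth)
plain_counts <- function(x) {
  x <- as.data.frame(x)[c("animal_id", "time_hours", "n", "organ",
                          "generation", "count")]
  rownames(x) <- NULL
  x
}

# flat Dirichlet draw on the 3-simplex
runif_simplex <- function() {
  x <- -log(runif(3))
  x / sum(x)
}

# single-type toy: generation-capped sink cells divide back into their own
# type, so (SPL, p) is a 1-type Galton-Watson process
single_type_toy <- function(gamma = 0.3, delta = 0.4) {
  model_parameters(gamma = c(0, 0, gamma), delta = c(0, 0, delta),
                   m = 0, rho = c(spl = 1, il = 0, mes = 0),
                   p = 2, migrating_generations = 1)
}
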