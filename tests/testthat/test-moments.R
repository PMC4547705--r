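test_that("one- and two-step moments match hand enumeration", {
  topo <- ref_topology(); th <- ref_params()
  ts <- build_type_space(topo, th$p)
  z0 <- numeric(nrow(ts)); z0[type_index(ts, "DR", 0)] <- 100
  ms <- propagate_moments(z0, th, topo, 2)

  i0 <- type_index(ts, "DR", 0); i1 <- type_index(ts, "DR", 1)
  i2 <- type_index(ts, "DR", 2); t1 <- type_index(ts, "TR2", 1)

  # one step: 100 cells each quiesce w.p. 0.43 or divide w.p. 0.06
  expect_equal(ms[[2]]$mean[i0], 43)
  expect_equal(ms[[2]]$mean[i1], 12)
  expect_equal(ms[[2]]$cov[i0, i0], 100 * 0.43 * 0.57)     # Bernoulli
  expect_equal(ms[[2]]$cov[i1, i1], 100 * (4 * 0.06 - 0.12^2))

  # two steps, linearity of the mean recursion
  expect_equal(ms[[3]]$mean[i0], 100 * 0.43^2)             # 18.49
  expect_equal(ms[[3]]$mean[i1], 43 * 0.12 + 12 * 0.31)    # 8.88
  expect_equal(ms[[3]]$mean[i2], 12 * 0.58)                # 6.96
  expect_equal(ms[[3]]$mean[t1], 12 * 0.14)                # 1.68 in transit

  # moment states stay coherent
  for (st in ms) {
    expect_true(all(st$mean >= 0))
    expect_equal(st$cov, t(st$cov))
    expect_gte(min(eigen(st$cov, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  expect_true(all(ms[[1]]$cov == 0))   # deterministic start
})

test_that("fast covariance recursion equals the per-type offspring covariance form", {
  topo <- ref_topology()
  set.seed(11)
  for (rep in 1:3) {
    g <- runif(3, 0, 0.3); d <- runif(3, 0, 0.3); m <- runif(1, 0, 0.2)
    r <- runif_simplex()
    th <- model_parameters(gamma = g, delta = d, m = m,
                           rho = c(spl = r[1], il = r[2], mes = r[3]))
    ops <- moment_operators(th, topo)
    ts <- ops$type_space
    D <- nrow(ts)
    mu <- rpois(D, 3)
    A <- matrix(rnorm(D * D, sd = 0.3), D, D); S <- crossprod(A)
    st1 <- step_moments(moment_state(mu, S), ops)
    # textbook recursion with explicit V_j
    Sig <- crossprod(ops$M, S %*% ops$M)
    for (j in seq_len(D)) {
      if (mu[j] == 0) next
      V <- offspring_covariance(ts$compartment[j], ts$generation[j], th, topo)
      Sig <- Sig + mu[j] * unname(V)
    }
    expect_equal(st1$cov, (Sig + t(Sig)) / 2, tolerance = 1e-8)
    expect_equal(st1$mean, unname(drop(crossprod(ops$M, mu))))
  }
})

test_that("the empty state is absorbing for the moment recursion", {
  topo <- ref_topology(); th <- ref_params()
  D <- nrow(build_type_space(topo, th$p))
  ms <- propagate_moments(numeric(D), th, topo, 4)
  for (st in ms) {
    expect_true(all(st$mean == 0))
    expect_true(all(st$cov == 0))
  }
})

test_that("sink arrival is delayed by exactly the transfer line", {
  topo <- ref_topology(); th <- ref_params()
  ts <- build_type_space(topo, th$p)
  z0 <- numeric(nrow(ts)); z0[type_index(ts, "DR", 1)] <- 100
  ms <- propagate_moments(z0, th, topo, 4)
  sink_idx <- which(ts$compartment %in% topo$sinks)
  for (n in 0:2) expect_true(all(ms[[n + 1]]$mean[sink_idx] == 0))
  # direct route: migrate (0.14), traverse, split towards the spleen (0.95)
  expect_equal(ms[[4]]$mean[type_index(ts, "SPL", 1)], 100 * 0.14 * 0.95)
  expect_gt(sum(ms[[4]]$mean[sink_idx]), 0)
})

test_that("a pure delay line conserves the expected population until sink death", {
  # no division/death anywhere, certain migration: cells just travel
  th <- model_parameters(gamma = c(0, 0, 0), delta = c(0, 0, 0), m = 1,
                         rho = c(spl = 0.95, il = 0.01, mes = 0.04),
                         migrating_generations = 1:6)
  topo <- ref_topology()
  ts <- build_type_space(topo, th$p)
  z0 <- numeric(nrow(ts)); z0[type_index(ts, "DR", 2)] <- 100
  ms <- propagate_moments(z0, th, topo, 4)
  expect_equal(vapply(ms, function(s) sum(s$mean), numeric(1)),
               c(100, 100, 100, 100, 0))   # sink cells die one step later
})

test_that("expected totals are non-increasing for subcritical offspring mass", {
  topo <- ref_topology()
  set.seed(21)
  for (rep in 1:3) {
    repeat {
      g <- runif(3, 0, 0.4); d <- runif(3, 0, 0.6); m <- runif(1, 0, 0.3)
      if (all(2 * g + d + m <= 1)) break
    }
    th <- model_parameters(gamma = g, delta = d, m = m,
                           rho = c(spl = 0.95, il = 0.01, mes = 0.04))
    ts <- build_type_space(topo, th$p)
    z0 <- numeric(nrow(ts))
    z0[type_index(ts, "DR", 0:4)] <- c(50, 100, 150, 100, 50)
    tot <- vapply(propagate_moments(z0, th, topo, 6),
                  function(s) sum(s$mean), numeric(1))
    expect_true(all(diff(tot) <= 1e-9))
  }
})

test_that("uniform fate scaling rescales means generation-wise and fixes per-organ frequencies", {
  # Under the pure-delay transfer line only the fate-driven transitions
  # scale: source means pick up c per step, while every sink lineage
  # traverses exactly K - 1 unscaled delay steps, so sink means scale as
  # c^(n - K + 1).  Per-organ frequency vectors are invariant either way;
  # only the organ totals carry the scale.
  topo <- ref_topology(); th <- ref_params()
  cc <- 0.8
  th_c <- model_parameters(gamma = cc * th$gamma, delta = cc * th$delta,
                           m = cc * th$m, rho = th$rho)
  ts <- build_type_space(topo, th$p)
  z0 <- numeric(nrow(ts))
  z0[type_index(ts, "DR", 0:4)] <- 1e4 * c(0.1, 0.25, 0.3, 0.25, 0.1)
  ms <- propagate_moments(z0, th, topo, 5)
  ms_c <- propagate_moments(z0, th_c, topo, 5)
  src <- which(ts$compartment == topo$source)
  K <- length(topo$transfer_stages)
  for (n in 0:5) {
    expect_equal(ms_c[[n + 1]]$mean[src], cc^n * ms[[n + 1]]$mean[src],
                 tolerance = 1e-12)
    for (org in topo$sinks) {
      oi <- which(ts$compartment == org)
      expect_equal(ms_c[[n + 1]]$mean[oi],
                   cc^max(0, n - K + 1) * ms[[n + 1]]$mean[oi],
                   tolerance = 1e-12)
      if (sum(ms[[n + 1]]$mean[oi]) > 0)
        expect_equal(frequency_moments(ms_c[[n + 1]], oi)$pi,
                     frequency_moments(ms[[n + 1]], oi)$pi,
                     tolerance = 1e-10)
    }
    if (n >= 1)
      expect_equal(frequency_moments(ms_c[[n + 1]], src)$pi,
                   frequency_moments(ms[[n + 1]], src)$pi,
                   tolerance = 1e-10)
  }

  # with proliferation in transit every transition is fate-driven, the
  # scaling is uniformly c^n, and even cross-organ frequencies are fixed
  th_t <- ref_params(proliferate_in_transit = TRUE)
  th_tc <- model_parameters(gamma = cc * th$gamma, delta = cc * th$delta,
                            m = cc * th$m, rho = th$rho,
                            proliferate_in_transit = TRUE)
  mt <- propagate_moments(z0, th_t, topo, 5)
  mt_c <- propagate_moments(z0, th_tc, topo, 5)
  meas <- which(ts$compartment %in% c(topo$source, topo$sinks))
  for (n in 0:5) {
    expect_equal(mt_c[[n + 1]]$mean, cc^n * mt[[n + 1]]$mean,
                 tolerance = 1e-12)
    if (n >= 1)
      expect_equal(frequency_moments(mt_c[[n + 1]], meas)$pi,
                   frequency_moments(mt[[n + 1]], meas)$pi,
                   tolerance = 1e-10)
  }
})

test_that("delta-method frequency moments match simulated frequencies", {
  topo <- ref_topology(); th <- ref_params()
  ts <- build_type_space(topo, th$p)
  z0 <- numeric(nrow(ts)); z0[type_index(ts, "DR", 0)] <- 100
  st <- propagate_moments(z0, th, topo, 1)[[2]]
  scope <- type_index(ts, "DR", 0:1)
  fm <- frequency_moments(st, scope)
  expect_equal(unname(fm$pi), c(43, 12) / 55, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(fm$omega))), 1e-10)

  # empirical single-step frequencies over a large ensemble; the delta
  # method is first-order, so the empirical mean is compared against the
  # second-order expansion E[Z1/S] ~ pi1 + (pi1 Var S - Cov(Z1, S)) / T^2
  n_paths <- 2e4
  ens <- simulate_ensemble(z0, th, topo, 1, n_paths, seed = 5)
  cnt <- ens[, 2, scope]
  tot <- rowSums(cnt)
  keep <- tot > 0
  f <- cnt[keep, 1] / tot[keep]
  S12 <- st$cov[scope, scope]
  varS <- sum(S12); cov1S <- sum(S12[1, ])
  bias2 <- (fm$pi[1] * varS - cov1S) / fm$total_mean^2
  se_mean <- sd(f) / sqrt(sum(keep))
  expect_lt(abs(mean(f) - (fm$pi[1] + bias2)), 5 * se_mean)
  v <- var(f)
  expect_lt(abs(v - fm$omega[1, 1]), 6 * v * sqrt(2 / sum(keep)) + 1e-8)

  # degenerate scopes
  one <- frequency_moments(st, type_index(ts, "DR", 0))
  expect_equal(unname(one$pi), 1)
  expect_true(all(one$omega == 0))
  expect_error(frequency_moments(st, type_index(ts, "SPL", 0:2)),
               "total mean")
})

test_that("structural reachability tracks the support of the mean trajectory", {
  topo <- ref_topology(); th <- ref_params()
  ts <- build_type_space(topo, th$p)
  z0 <- numeric(nrow(ts))
  z0[type_index(ts, "DR", 0:4)] <- c(1, 1, 1, 1, 1) * 100
  reach <- reachable_types(z0, th, topo, 6)
  ms <- propagate_moments(z0, th, topo, 6)
  for (n in 0:6)
    expect_equal(unname(reach[n + 1, ]), unname(ms[[n + 1]]$mean > 0))
  # stage 1 is traversed within the egress step, never occupied at a snapshot
  expect_true(all(!reach[, ts$compartment == "TR1"]))
  # sinks light up exactly at the transit time, with the migrating generations
  sink1 <- type_index(ts, "SPL", 1:3)
  expect_true(all(reach[4, sink1]))
  expect_false(any(reach[3, ts$compartment %in% topo$sinks]))
})
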