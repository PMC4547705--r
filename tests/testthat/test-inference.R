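test_that("reduced Gaussian frequency term matches hand arithmetic", {
  # 2 categories, last dropped: a 1-dimensional normal
  pi <- c(0.8, 0.2)
  Om <- matrix(c(0.01, -0.01, -0.01, 0.01), 2, 2)
  f <- c(0.9, 0.1)
  term <- mgwnet:::freq_nll_term(f, pi, Om, jitter = 0)
  # quadratic part: 0.5 * 0.1^2 / 0.01 = 0.5
  expect_equal(term$value - 0.5 * (log(2 * base::pi) + log(0.01)), 0.5,
               tolerance = 1e-10)
  expect_false(term$singular)

  # exact-frequency data contribute only the log-determinant part
  t0 <- mgwnet:::freq_nll_term(pi, pi, Om, jitter = 0)
  expect_equal(t0$value, 0.5 * (log(2 * base::pi) + log(0.01)),
               tolerance = 1e-10)

  # doubling the deviation quadruples the quadratic part
  t2 <- mgwnet:::freq_nll_term(c(1.0, 0.0), pi, Om, jitter = 0)
  expect_equal(t2$value - t0$value, 4 * (term$value - t0$value),
               tolerance = 1e-10)
})

test_that("the likelihood is deterministic and penalizes invalid parameters", {
  data <- small_dataset(seed = 3)
  th <- ref_params(); topo <- ref_topology()
  z0 <- initial_state_from_data(data, th, topo)
  l1 <- negative_log_likelihood(th, data, z0, topo)
  l2 <- negative_log_likelihood(th, data, z0, topo)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_true(is.finite(l1))
  expect_gt(attr(l1, "n_terms"), 0)

  bad <- as_theta(th); bad["delta1"] <- 0.9     # 0.9 + 0.29 + 0.14 > 1
  expect_identical(as.numeric(negative_log_likelihood(bad, data, z0, topo)),
                   Inf)

  # an unnormalized rho is rejected normally but tolerated in
  # sensitivity mode
  odd <- as_theta(th); odd["rho_spl"] <- 0.95 * 1.1
  expect_identical(as.numeric(negative_log_likelihood(odd, data, z0, topo)),
                   Inf)
  expect_true(is.finite(negative_log_likelihood(
    odd, data, z0, topo, allow_unnormalized_rho = TRUE)))
})

test_that("the likelihood prefers the generating parameters on average", {
  topo <- ref_topology(); th <- ref_params()
  theta0 <- as_theta(th)
  perturb <- c("delta0", "gamma1", "m", "rho_spl")
  diffs <- matrix(0, 10, length(perturb) * 2,
                  dimnames = list(NULL, paste(rep(perturb, each = 2),
                                              c("down", "up"))))
  for (r in 1:10) {
    data <- small_dataset(seed = 300 + r)
    z0 <- initial_state_from_data(data, th, topo)
    l0 <- as.numeric(negative_log_likelihood(th, data, z0, topo))
    k <- 0
    for (p in perturb) for (s in c(-0.2, 0.2)) {
      k <- k + 1
      thp <- theta0
      thp[p] <- thp[p] * (1 + s)
      if (p == "rho_spl")  # keep the simplex: absorb into rho_mes
        thp["rho_mes"] <- 1 - thp["rho_spl"] - thp["rho_il"]
      diffs[r, k] <- as.numeric(negative_log_likelihood(thp, data, z0, topo)) - l0
    }
  }
  # on average over replicates, every 20% perturbation raises the NLL
  expect_true(all(colMeans(diffs) > 0))
})

test_that("an estimate initialized at the truth stays near the truth on a large design", {
  topo <- ref_topology(); th <- ref_params()
  data <- small_dataset(seed = 17, animals = 40,
                        initial = 5e4 * c(0.10, 0.25, 0.30, 0.25, 0.10))
  z0 <- initial_state_from_data(data, th, topo)
  prep <- mgwnet:::prep_likelihood(data, th, topo, z0, "global")
  obj <- function(t9) {
    pr <- mgwnet:::project_reduced(t9, th)
    params <- theta_to_parameters(mgwnet:::reduced_to_theta(pr$th), th,
                                  validate = FALSE)
    v <- mgwnet:::nll_prepared(params, prep, topo)
    if (!is.finite(v)) 1e12 else as.numeric(v) + 1e6 * pr$overshoot^2
  }
  t_true <- as_theta(th)[1:9]
  o <- optim(t_true, obj, method = "L-BFGS-B",
             lower = rep(1e-4, 9), upper = rep(1 - 1e-4, 9),
             control = list(maxit = 300, factr = 1e7))
  expect_lte(o$value, obj(t_true) + 1e-8)
  expect_lt(max(abs(o$par - t_true)), 0.02)
})

test_that("parameter recovery sharpens as animals per step grow", {
  topo <- ref_topology(); th <- ref_params()
  err <- sapply(c(5, 20), function(A) {
    data <- small_dataset(seed = 41, animals = A,
                          initial = 5e4 * c(0.10, 0.25, 0.30, 0.25, 0.10))
    fit <- fit_mle(data, topology = topo, starts = 6, seed = 5,
                   compute_se = FALSE, control = quick_control)
    max(abs(fit$theta - as_theta(th))[c("delta0", "gamma1", "m", "rho_spl")])
  })
  expect_lt(err[1], 0.08)
  expect_lt(err[2], 0.05)
})

test_that("rho is flagged non-identifiable when no cells reach the sinks", {
  topo <- ref_topology()
  th0 <- ref_params(m = 0)
  data <- small_dataset(seed = 9, params = th0)
  expect_equal(sum(data$count[data$organ %in% topo$sinks]), 0)
  expect_warning(
    fit <- fit_mle(data, topology = topo, starts = 3, seed = 2,
                   compute_se = TRUE, control = quick_control),
    "not identifiable")
  expect_false(fit$rho_identifiable)
  expect_true(all(is.na(fit$theta[c("rho_spl", "rho_il", "rho_mes")])))
  expect_true(all(is.na(fit$se[c("rho_spl", "rho_il", "rho_mes")])))
})

test_that("Fisher standard errors reproduce the Gaussian closed form and scale with design size", {
  # quadratic toy cost: NLL = (theta - 0.5)^2 / (2 * 0.01) has SE = 0.1
  toy <- mgwnet:::hessian_se(function(t) (t - 0.5)^2 / (2 * 0.01), 0.5)
  expect_equal(toy$se, 0.1, tolerance = 1e-6)
  expect_false(toy$singular)

  # information adds over independent animals: 4x animals halves the SE
  topo <- ref_topology(); th <- ref_params()
  se_by_A <- sapply(c(5, 20), function(A) {
    data <- small_dataset(seed = 23, animals = A,
                          initial = 5e4 * c(0.10, 0.25, 0.30, 0.25, 0.10))
    z0 <- initial_state_from_data(data, th, topo)
    fisher_standard_errors(th, data, z0, topo)$se
  })
  ratio <- se_by_A[, 1] / se_by_A[, 2]
  for (p in c("delta0", "gamma1", "m", "rho_spl"))
    expect_lt(abs(ratio[[p]] - 2), 0.8)
})

test_that("reported standard errors track the replicate spread of the estimator", {
  topo <- ref_topology(); th <- ref_params()
  n_rep <- 12
  est <- matrix(NA_real_, n_rep, 10)
  ses <- matrix(NA_real_, n_rep, 10)
  for (r in seq_len(n_rep)) {
    data <- small_dataset(seed = 500 + r, animals = 5,
                          initial = 5e4 * c(0.10, 0.25, 0.30, 0.25, 0.10))
    fit <- fit_mle(data, topology = topo, starts = 4, seed = r,
                   control = quick_control)
    est[r, ] <- fit$theta
    ses[r, ] <- fit$se
  }
  emp_sd <- apply(est, 2, sd)
  mean_se <- colMeans(ses)
  for (k in c(1, 4, 7, 8)) {      # delta0, gamma1, m, rho_spl
    expect_lt(mean_se[k] / emp_sd[k], 3)
    expect_gt(mean_se[k] / emp_sd[k], 1 / 3)
  }
})

test_that("sensitivity statistic matches hand arithmetic and degenerate cases", {
  # toy cost L(theta) = theta^2 at theta_hat = 1: Delta = +0.1 gives
  # S = (0.21 / 1) / 0.1 = 2.1
  S <- mgwnet:::sensitivity_profile(function(th) th[1]^2, 1, 1,
                                    deltas_rel = 0.1)
  expect_equal(S, 2.1, tolerance = 1e-12)

  # a cost that ignores the parameter has zero sensitivity
  S0 <- mgwnet:::sensitivity_profile(function(th) 5, 1, 1,
                                     deltas_rel = c(-0.1, 0.05, 0.1))
  expect_equal(S0, c(0, 0, 0))

  # zero optimized cost leaves the statistic undefined
  expect_error(mgwnet:::sensitivity_profile(function(th) 0, 1, 1, 0.1),
               "undefined sensitivity")
})

test_that("sensitivity profiles cover the grid and respect the rho convention", {
  topo <- ref_topology(); th <- ref_params()
  data <- small_dataset(seed = 31)
  z0 <- initial_state_from_data(data, th, topo)
  prof <- relative_sensitivity(th, data, z0, topo,
                               parameters = c("delta0", "rho_spl"),
                               n_grid = 11)
  expect_s3_class(prof, "mgw_sensitivity")
  expect_equal(nrow(prof), 2 * 10)          # center point excluded
  expect_true(all(is.finite(prof$S)))
  expect_true(all(prof$S >= 0))
  s <- summary(prof)
  expect_named(s, c("parameter", "max_S"))
  # renormalized perturbation gives a different (finite) profile
  prof2 <- relative_sensitivity(th, data, z0, topo, parameters = "rho_spl",
                                n_grid = 11, renormalize_rho = TRUE)
  expect_true(all(is.finite(prof2$S)))
  expect_false(isTRUE(all.equal(prof$S[prof$parameter == "rho_spl"],
                                prof2$S)))
})

test_that("the likelihood is equivariant under sink relabeling", {
  # swap the iliac and mesenteric labels in both the topology wiring and
  # the data: the likelihood of the correspondingly swapped parameters is
  # unchanged
  topo <- ref_topology()
  topo_sw <- network_topology(sinks = c(SPL = "spl", ILN = "mes", MLN = "il"))
  th <- ref_params()
  th_sw <- ref_params(rho = c(spl = 0.95, il = 0.04, mes = 0.01))
  data <- small_dataset(seed = 13)
  z0 <- initial_state_from_data(data, th, topo)
  l <- negative_log_likelihood(th, data, z0, topo)
  l_sw <- negative_log_likelihood(th_sw, data, z0, topo_sw)
  expect_equal(as.numeric(l), as.numeric(l_sw), tolerance = 1e-10)
})
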