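test_that("noiseless power-law data are recovered exactly", {
  r <- c(1/8, 1/4, 1/2, 1, 2, 4, 8)
  # exact data: lm warns that the fit is perfect, which is the point here
  f1 <- suppressWarnings(fit_matching_law(r, r^1))
  expect_equal(f1$beta_hat, 1, tolerance = 1e-10)
  expect_equal(f1$k_hat, 1, tolerance = 1e-10)
  f2 <- suppressWarnings(fit_matching_law(r, 2 * r^0.8))
  expect_equal(f2$beta_hat, 0.8, tolerance = 1e-10)
  expect_equal(f2$k_hat, 2, tolerance = 1e-10)
  expect_error(fit_matching_law(r, c(-1, r[-1]^0.8)), "positive")
  expect_error(fit_matching_law(c(1, 2), c(1, 2)), "3")
})

test_that("undermatching in noisy synthetic data is detected", {
  set.seed(8)
  r <- rep(c(1/8, 1/4, 1/2, 1, 2, 4, 8), each = 8)
  occ <- r^0.9 * exp(rnorm(length(r), 0, 0.2))
  f <- fit_matching_law(r, occ)
  expect_lt(f$beta_hat + 2 * f$stderr_beta, 1)
  expect_gt(f$beta_hat - 2 * f$stderr_beta, 0.75)
})

test_that("langevin engine recovers known exponents across a beta grid", {
  spec <- matching_spec(ratios = c(1/8, 1, 8), n_rep = 6, T = 10000)
  for (beta in c(0.5, 1.0)) {
    lp <- langevin_params(D = 10, chi = 10 * beta)
    res <- run_matching_experiment(spec, engine = "langevin",
                                   seed = round(100 * beta), langevin = lp)
    expect_lt(abs(res$beta_hat - beta), 2.5 * res$stderr_beta)
  }
})

test_that("a multiplicative preference bias moves k_hat, not beta_hat", {
  lp <- langevin_params(D = 10, chi = 8)
  spec_b <- matching_spec(ratios = c(1/4, 1, 4), n_rep = 6, T = 10000,
                          bias = 2)
  res_b <- run_matching_experiment(spec_b, engine = "langevin", seed = 51,
                                   langevin = lp)
  # bias c multiplies R1: P1/P2 = (c ratio)^beta = c^beta ratio^beta,
  # so k_hat estimates c^beta while beta_hat is unchanged
  expect_lt(abs(res_b$beta_hat - 0.8), 2.5 * res_b$stderr_beta)
  expect_equal(log(res_b$k_hat), 0.8 * log(2),
               tolerance = 3 * res_b$stderr_log_k / (0.8 * log(2)))
})

test_that("beta_hat scales with mu/d0 and not with v0 or tau", {
  spec <- matching_spec(ratios = c(1/4, 1, 4), n_rep = 5, T = 8000)
  base <- run_matching_experiment(spec, agent_params(),
                                  engine = "langevin", seed = 61,
                                  circuit = matching_default_circuit())
  # doubling v0 (and with it D and chi) leaves the exponent alone
  fast <- run_matching_experiment(spec, agent_params(v0 = 20),
                                  engine = "langevin", seed = 62,
                                  circuit = matching_default_circuit())
  joint <- sqrt(base$stderr_beta^2 + fast$stderr_beta^2)
  expect_lt(abs(base$beta_hat - fast$beta_hat), 3 * joint)
  # halving the gain halves the exponent
  half <- run_matching_experiment(spec, agent_params(),
                                  engine = "langevin", seed = 63,
                                  circuit = matching_default_circuit(mu = 2))
  expect_lt(abs(half$beta_hat - base$beta_hat / 2),
            2.5 * sqrt(half$stderr_beta^2 + base$stderr_beta^2 / 4))
  # doubling d0 at fixed mu does the same
  dbl <- run_matching_experiment(spec, agent_params(),
                                 engine = "langevin", seed = 64,
                                 circuit = matching_default_circuit(d0 = 10))
  expect_lt(abs(dbl$beta_hat - base$beta_hat / 2),
            2.5 * sqrt(dbl$stderr_beta^2 + base$stderr_beta^2 / 4))
})

test_that("v0/tau independence holds for the mechanistic agent too", {
  spec <- matching_spec(ratios = c(1/4, 1, 4), n_rep = 5, T = 6000)
  cc <- matching_default_circuit()
  base <- suppressWarnings(run_matching_experiment(spec, agent_params(), cc,
                                  engine = "taxis", seed = 71))
  slow_tumble <- suppressWarnings(
    run_matching_experiment(spec, agent_params(tau = 0.05), cc,
                            engine = "taxis", seed = 72))
  joint <- sqrt(base$stderr_beta^2 + slow_tumble$stderr_beta^2)
  expect_lt(abs(base$beta_hat - slow_tumble$beta_hat), 3 * joint)
})

test_that("empty-window replicates are dropped with a warning", {
  # replicates of essentially zero duration never reach the far window;
  # they are all flagged, and with nothing left the fit refuses to run
  spec <- matching_spec(ratios = c(1/2, 1, 2), n_rep = 2, T = 2)
  lp <- langevin_params(D = 10, chi = 8)
  expect_warning(
    expect_error(run_matching_experiment(spec, engine = "langevin",
                                         seed = 81, langevin = lp),
                 "3 pairs"),
    "empty window")
})
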