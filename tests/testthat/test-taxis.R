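test_that("agent parameters are validated", {
  expect_error(agent_params(v0 = -1), "v0")
  expect_error(agent_params(tau = 0), "tau")
  expect_error(agent_params(m = 4), "m")
  expect_error(simulate_taxis(agent_params(tau = 0.1),
                              circuit_params(), make_uniform_field(),
                              T = 1, dt = 0.2), "dt")
})

test_that("uniform field: no sensing, pure diffusion with D = v0^2 tau", {
  ag <- agent_params(v0 = 10, tau = 0.1, m = 1)
  cc <- mouse()
  fld <- make_uniform_field(1, 1)
  disp <- vapply(1:150, function(s) {
    tr <- simulate_taxis(ag, cc, fld, T = 40, dt = 0.005, seed = s,
                         box = "none", record_dt = 40)
    tail(tr$positions[, 1], 1)
  }, numeric(1))
  # dopamine pinned at baseline, speed at v0: unbiased
  expect_lt(abs(mean(disp)) / sd(disp) * sqrt(150), 3.5)
  D_eff <- mean(disp^2) / (2 * 40)
  expect_equal(D_eff, 10, tolerance = 0.2)
})

test_that("zero gain gives an unbiased walk even in a steep field", {
  ag <- agent_params(v0 = 10, tau = 0.1, m = 1)
  cc <- circuit_params(mu = 0)
  fld <- fig3_field(8)
  disp <- vapply(1:60, function(s) {
    tr <- simulate_taxis(ag, cc, fld, T = 30, dt = 0.005, seed = s,
                         box = "none", x_init = 10, record_dt = 30)
    tail(tr$positions[, 1], 1) - 10
  }, numeric(1))
  expect_lt(abs(mean(disp)) / (sd(disp) / sqrt(60)), 3.5)
})

test_that("trajectories are reproducible bit-for-bit under a fixed seed", {
  ag <- agent_params()
  cc <- mouse()
  fld <- fig3_field(4)
  t1 <- simulate_taxis(ag, cc, fld, T = 20, dt = 0.005, seed = 99,
                       centers = c(30, -30))
  t2 <- simulate_taxis(ag, cc, fld, T = 20, dt = 0.005, seed = 99,
                       centers = c(30, -30))
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$d, t2$d)
  expect_identical(t1$occupancy, t2$occupancy)
  t3 <- simulate_taxis(ag, cc, fld, T = 20, dt = 0.005, seed = 100)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("residence time accounting is consistent", {
  # a trajectory pinned by zero speed: h_speed irrelevant, use v0 tiny
  ag <- agent_params(v0 = 1e-9, tau = 0.1)
  fld <- fig3_field(1)
  tr <- simulate_taxis(ag, mouse(), fld, T = 10, dt = 0.005, seed = 1,
                       x_init = 30, centers = c(30, -30), record_dt = 0.01)
  expect_equal(tr$occupancy[1], 10, tolerance = 1e-6)
  expect_equal(tr$occupancy[2], 0)
  rt <- residence_times(tr, c(30, -30))
  expect_equal(rt[1], 10, tolerance = 0.05)
  expect_equal(rt[2], 0)
  expect_error(residence_times(list(times = numeric(0),
                                    positions = NULL), 0), "empty")
})

test_that("symmetric rewards give symmetric occupancy", {
  ag <- agent_params()
  cc <- matching_default_circuit()
  fld <- fig3_field(1)
  occ <- Reduce(`+`, lapply(1:6, function(s) {
    simulate_taxis(ag, cc, fld, T = 4000, dt = 0.005, seed = 300 + s,
                   x_init = c(30, -30)[1 + s %% 2], centers = c(30, -30),
                   record_dt = 1000)$occupancy
  }))
  expect_equal(occ[1] / occ[2], 1, tolerance = 0.35)
})

test_that("empirical drift matches chi grad log R in a shallow field", {
  # constant-gradient field (h = 1); coarse-graining regime
  gamma <- 0.02
  ag <- agent_params(v0 = 10, tau = 0.1, m = 1)
  cc <- matching_default_circuit()
  fld <- make_expdecay_field(gamma_field = gamma, h_field = 1)
  lp <- coefficients_from_mechanism(ag, cc)
  T_run <- 600
  disp <- vapply(1:1500, function(s) {
    tr <- simulate_taxis(ag, cc, fld, T = T_run, dt = 0.005, seed = 700 + s,
                         x_init = 4000, box = "none", record_dt = T_run)
    tail(tr$positions[, 1], 1) - 4000
  }, numeric(1))
  drift_emp <- mean(disp) / T_run
  drift_pred <- lp$chi * (-gamma)
  expect_equal(drift_emp, drift_pred, tolerance = 0.15)
})

test_that("speed- and tumble-modulation give compatible matching exponents", {
  spec <- matching_spec(ratios = c(1/4, 1, 4), n_rep = 6, T = 8000)
  cc <- matching_default_circuit()
  r_speed <- suppressWarnings(run_matching_experiment(spec, agent_params(), cc,
                                     engine = "taxis", seed = 21))
  r_tumble <- suppressWarnings(run_matching_experiment(spec,
                                      agent_params(modulation = "tumble"),
                                      cc, engine = "taxis", seed = 22))
  joint_se <- sqrt(r_speed$stderr_beta^2 + r_tumble$stderr_beta^2)
  expect_lt(abs(r_speed$beta_hat - r_tumble$beta_hat), 3 * joint_se)
})

test_that("mechanistic coefficients evaluate the printed formulas", {
  lp <- coefficients_from_mechanism(agent_params(v0 = 10, tau = 0.1, m = 1),
                                    circuit_params(mu = 4, d0 = 5))
  expect_equal(lp$D, 10)
  expect_equal(lp$chi, 8)
  expect_equal(lp$beta, 0.8)
  expect_equal(coefficients_from_mechanism(agent_params(),
                                           circuit_params(mu = 0))$chi, 0)
  expect_equal(coefficients_from_mechanism(agent_params(m = 2),
                                           circuit_params())$D, 5)
  # nonlinear speed gain multiplies chi (and beta) by h
  lp2 <- coefficients_from_mechanism(agent_params(h_speed = 2),
                                     circuit_params(mu = 4, d0 = 5))
  expect_equal(lp2$beta, 1.6)
})
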