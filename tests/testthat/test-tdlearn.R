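test_that("log-TD update arithmetic matches the rule", {
  p <- td_params(alpha_lr = 0.02, gamma_disc = 0.9)
  tab <- c(0, 0, 0)
  # perfect prediction: r + gamma V(s') = V(s) => no change
  tab2 <- log_td_update(tab, 1, 2, r = 1 - 0.9, p)
  expect_equal(tab2[1], 0, tolerance = 1e-12)
  # logV(s)=0, r=0, gamma V(s') = e => update alpha (e - 1)
  tab3 <- c(0, log(exp(1) / 0.9))
  tab3 <- log_td_update(tab3, 1, 2, r = 0, p)
  expect_equal(tab3[1], 0.02 * (exp(1) - 1), tolerance = 1e-12)
  # small errors: log-TD ~ alpha * delta_log (first order)
  for (dl in c(1e-3, -1e-3, 5e-3)) {
    tb <- c(1, (1 + dl - log(0.9)))
    upd <- log_td_update(tb, 1, 2, r = 0, p)[1] - 1
    expect_equal(upd, 0.02 * dl, tolerance = 1e-2)
  }
  # zero target is allowed (e^delta_log = 0); negative is a domain error
  tz <- log_td_update(c(0, 0), 1, NA, r = 0, p)
  expect_equal(tz[1], -0.02, tolerance = 1e-12)
  expect_error(log_td_update(c(0, 0), 1, NA, r = -1, p), "non-negative")
})

test_that("classic TD update and its dynamic-programming fixed point", {
  p <- td_params(alpha_lr = 0.1, gamma_disc = 0.9)
  tab <- c(1, 1)
  tab <- classic_td_update(tab, 1, 2, r = 1, p)
  expect_equal(tab[1], 1 + 0.1 * (1 + 0.9 - 1), tolerance = 1e-12)
  # converged chain values equal gamma^(distance) * E[r]
  pr <- td_params(alpha_lr = 0.1, gamma_disc = 0.8, N = 4,
                  episodes = 3000, magnitude = 10)
  res <- run_chain_experiment(pr, rule = "classic")
  expect_equal(res$logV_final, log(0.8^(3:0) * 10), tolerance = 1e-4)
})

test_that("the chain converges to the analytic discounted value", {
  p50 <- td_params(magnitude = 50, episodes = 6000)
  res50 <- run_chain_experiment(p50, seed = 1)
  expect_equal(res50$target, log(0.9^4 * 50), tolerance = 1e-12)
  expect_equal(res50$converged_value, res50$target, tolerance = 1e-2)
  # reward magnitude enters additively on the log scale
  res200 <- run_chain_experiment(td_params(magnitude = 200,
                                           episodes = 6000), seed = 1)
  expect_equal(res200$converged_value - res50$converged_value, log(4),
               tolerance = 1e-3)
})

test_that("stochastic reward models share the deterministic target", {
  eps <- 15000
  det <- run_chain_experiment(td_params(magnitude = 50, episodes = eps),
                              seed = 2)
  nrm <- run_chain_experiment(td_params(magnitude = 50, episodes = eps,
                                        reward_model = "normal_cv"),
                              seed = 3)
  brn <- run_chain_experiment(td_params(magnitude = 50, episodes = eps,
                                        reward_model = "bernoulli"),
                              seed = 4)
  expect_equal(nrm$converged_value, det$target, tolerance = 0.05)
  expect_equal(brn$converged_value, det$target, tolerance = 0.1)
})

test_that("rescaling rewards shifts the learned log-values by log lambda", {
  lam <- 7
  a <- run_chain_experiment(td_params(magnitude = 50,
                                      reward_model = "bernoulli",
                                      episodes = 800), seed = 6,
                            logV_init = 0)
  b <- run_chain_experiment(td_params(magnitude = 50 * lam,
                                      reward_model = "bernoulli",
                                      episodes = 800), seed = 6,
                            logV_init = log(lam))
  # the whole trajectory maps exactly: the update depends only on ratios
  expect_equal(b$logV_S1, a$logV_S1 + log(lam), tolerance = 1e-10)
  expect_equal(b$logV_final, a$logV_final + log(lam), tolerance = 1e-10)
})

test_that("expected update vanishes exactly at the classic TD fixed point", {
  p <- td_params(gamma_disc = 0.9, reward_model = "bernoulli",
                 magnitude = 20, p_bern = 0.25)
  # V(s) = E[r + gamma V(s')]: rewards 80 w.p. 1/4 (terminal, V'=0)
  V_fix <- 20
  tab <- c(log(V_fix))
  up_hi <- log_td_update(tab, 1, NA, r = 80, p)[1] - log(V_fix)
  up_lo <- log_td_update(tab, 1, NA, r = 0, p)[1] - log(V_fix)
  expect_equal(0.25 * up_hi + 0.75 * up_lo, 0, tolerance = 1e-12)
})

test_that("converged values drive the circuit response of the TD bridge", {
  # after learning, delivery of the mean reward from state S_{N-1} gives
  # Delta d = mu * delta_log evaluated at the learned values
  res <- run_chain_experiment(td_params(magnitude = 50, episodes = 6000),
                              seed = 9)
  V <- exp(res$logV_final)
  p <- mouse()
  resp <- reward_response_after_adaptation(p, V_s = V[5], r = 50,
                                           V_sprime = 0)
  # learned V(S5) ~ E[r] = 50: a fulfilled prediction, near-zero response
  expect_lt(abs(resp), 0.1)
  # an unrewarded step to the successor is also fully predicted
  resp_step <- reward_response_after_adaptation(p, V_s = V[4], r = 0,
                                                V_sprime = V[5] * 0.9)
  expect_lt(abs(resp_step), 0.2)
})
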