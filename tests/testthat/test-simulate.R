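test_that("simulation is reproducible from its seed", {
  d <- two_stage_design()
  a <- estimate_error_rates(d, n_reps = 5e3, seed = 11)
  b <- estimate_error_rates(d, n_reps = 5e3, seed = 11)
  expect_identical(a, b)
  c <- estimate_error_rates(d, n_reps = 5e3, seed = 12)
  expect_false(identical(a$fwer, c$fwer))

  # the simulate() method is a front end to the same estimator
  s <- simulate(d, nsim = 5e3, seed = 11)
  expect_identical(s, a)
  expect_error(simulate(d, nsim = 10), "seed")
})

test_that("marginal and joint calibration of the simulated statistics", {
  d1 <- mams_design(1, 1, 1, alpha = 0.025, omega = 0.9, control_events = 100,
                    target_effect_I = log(0.75), target_effect_D = log(0.75))
  n <- 2e5
  sim <- estimate_error_rates(d1, n_reps = n, seed = 5)
  expect_lt(abs(sim$pwer_per_arm[1] - 0.025), 3 * sqrt(0.025 * 0.975 / n))

  # between-stage correlation of the drawn statistics matches sqrt(e_1/e_4)
  d <- stampede_design()
  z <- simulate_trial_stats(d, n_reps = 1e5, seed = 6)
  r_emp <- cor(z[, "Z1.1"], z[, "Z4.1"])
  r_th <- sqrt(113 / 403)
  expect_lt(abs(r_emp - r_th), 3 * (1 - r_th^2) / sqrt(1e5))

  # between-arm correlation at a fixed stage matches A/(A+1)
  r_arm <- cor(z[, "Z4.1"], z[, "Z4.2"])
  expect_lt(abs(r_arm - 1 / 3), 3 * (1 - (1 / 3)^2) / sqrt(1e5))
})

test_that("infinite intermediate effects act as pass/fail sentinels", {
  d <- two_stage_design(K = 2)
  z <- simulate_trial_stats(d, effect_scenario(d, c(-Inf, Inf), c(0, 0)),
                            n_reps = 100, seed = 2)
  expect_true(all(z[, "Z1.1"] == -Inf))  # always passes the interim
  expect_true(all(z[, "Z1.2"] == Inf))   # never passes
  expect_true(all(is.finite(z[, c("Z2.1", "Z2.2")])))

  sim <- estimate_error_rates(d, effect_scenario(d, c(-Inf, Inf), c(0, 0)),
                              n_reps = 2e4, seed = 2)
  expect_equal(sim$pwer_per_arm[2], 0)   # dropped arm cannot reject
  expect_gt(sim$pwer_per_arm[1], 0)
})

test_that("simulation agrees with the analytic error rates under the global null", {
  d <- stampede_design()
  n <- 2e5
  sim <- estimate_error_rates(d, n_reps = n, seed = 8)
  p <- pairwise_error(d)$value
  for (k in 1:5)
    expect_lt(abs(sim$pwer_per_arm[k] - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the maximising scenario reproduces the Dunnett maximum FWER", {
  # two-stage two-arm designs: arms certain to pass the interim, null on D
  d <- two_stage_design(K = 2)
  n <- 4e5
  sim <- estimate_error_rates(d, effect_scenario(d, -Inf, 0),
                              n_reps = n, seed = 21)
  fw <- max_fwer(d)$value           # 0.045 for K = 2, A = 1, alpha_J = 0.025
  expect_lt(abs(sim$fwer - fw), 3 * sqrt(fw * (1 - fw) / n))
  expect_equal(round(fw, 3), 0.045)

  # non-binding boundaries: every null arm rejects at alpha_J regardless of I
  d_nb <- two_stage_design(K = 2, binding = FALSE)
  sim_nb <- estimate_error_rates(d_nb, null_scenario(d_nb),
                                 n_reps = n, seed = 22)
  for (k in 1:2)
    expect_lt(abs(sim_nb$pwer_per_arm[k] - 0.025),
              3 * sqrt(0.025 * 0.975 / n))
})

test_that("familywise error dominates the pairwise error, with equality at one arm", {
  scenarios <- list(
    list(d = two_stage_design(K = 2), th = 0),
    list(d = two_stage_design(K = 2), th = -0.223),
    list(d = stampede_design(), th = -0.105)
  )
  for (s in scenarios) {
    sim <- estimate_error_rates(s$d, effect_scenario(s$d, s$th, 0),
                                n_reps = 5e4, seed = 31)
    expect_gte(sim$fwer, max(sim$pwer_per_arm, na.rm = TRUE))
    expect_equal(sim$mc_se_fwer, sqrt(sim$fwer * (1 - sim$fwer) / sim$n_reps))
  }
  d1 <- mams_design(2, 1, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                    control_events = c(72, 200),
                    target_effect_I = log(0.75), target_effect_D = log(0.75))
  sim1 <- estimate_error_rates(d1, n_reps = 5e4, seed = 32)
  expect_equal(sim1$fwer, sim1$pwer_per_arm[1])
})

test_that("strong intermediate effects reach the plateau regime", {
  # all arms at HR 0.5 on I: interim passage is near-certain
  d <- two_stage_design(K = 2)
  n <- 2e5
  sim <- estimate_error_rates(d, effect_scenario(d, log(0.5), 0),
                              n_reps = n, seed = 41)
  fw <- max_fwer(d)$value
  expect_lt(abs(sim$fwer - fw), 3 * sqrt(fw * (1 - fw) / n))
})

test_that("sweeping the intermediate effect traces the published trends", {
  d <- two_stage_design(K = 2)
  n <- 1e5
  grid <- c(0, log(0.9), log(0.8), -Inf)
  sw <- scenario_sweep(d, grid, n_reps = n, seed = 51)
  expect_s3_class(sw, "mams_sweep")
  expect_equal(nrow(sw), 4)

  # single-point grid reproduces the global-null estimate
  point <- estimate_error_rates(d, null_scenario(d), n_reps = n, seed = 51)
  expect_equal(sw$fwer[1], point$fwer)

  # FWER non-decreasing as the effect on I strengthens (matched seeds),
  # final entry at the Dunnett maximum
  expect_true(all(diff(sw$fwer) >= 0))
  fw <- max_fwer(d)$value
  expect_lt(abs(sw$fwer[4] - fw), 3 * sqrt(fw * (1 - fw) / n))

  # varying one arm inflates the FWER less than varying both
  sw1 <- scenario_sweep(d, log(0.8), which_arms = 1, n_reps = n, seed = 51)
  both_gain <- sw$fwer[3] - sw$fwer[1]
  one_gain <- sw1$fwer[1] - sw$fwer[1]
  expect_lt(one_gain, both_gain)
  expect_gt(one_gain, 0)

  expect_error(scenario_sweep(d, numeric(0), n_reps = 10, seed = 1), "empty")
  expect_error(scenario_sweep(d, 0, which_arms = 9, n_reps = 10, seed = 1),
               "arms")
})
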