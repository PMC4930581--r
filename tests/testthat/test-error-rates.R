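test_that("single-stage and degenerate orthant probabilities are exact", {
  d1 <- mams_design(1, 1, 1, alpha = 0.025, omega = 0.9, control_events = 100,
                    target_effect_I = log(0.75), target_effect_D = log(0.75))
  expect_equal(pairwise_error(d1)$value, 0.025)
  expect_equal(pairwise_power(d1)$value, 0.9)
  expect_equal(max_pairwise_error(d1)$value, 0.025)  # no interim stages
  expect_equal(max_fwer(d1)$value, 0.025)            # one arm: FWER = PWER

  # independent coordinates multiply; perfectly correlated take the minimum
  expect_equal(mamsio:::mvn_lower(qnorm(c(0.5, 0.025)), diag(2)), 0.0125,
               tolerance = 1e-8)
  d_tied <- mams_design(2, 1, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.90),
                        control_events = c(100, 100),
                        target_effect_I = log(0.75), target_effect_D = log(0.75))
  expect_equal(pairwise_power(d_tied)$value, 0.90)
  expect_equal(pairwise_error(d_tied)$value, 0.025)
})

test_that("multi-stage orthant values match an independent Monte-Carlo evaluation", {
  d <- stampede_design()
  # frozen values of the 4-dimensional lower-orthant probability with the
  # nested-events correlation; cross-checked below by simulation
  expect_equal(pairwise_error(d)$value, 0.0213150, tolerance = 1e-5)
  expect_equal(pairwise_power(d)$value, 0.8552283, tolerance = 1e-5)

  # independent check: direct multivariate draw at the z-statistic level
  set.seed(314)
  n <- 4e5
  R <- between_stage_corr(d)
  z <- matrix(rnorm(n * 4), n) %*% chol(R)
  hit <- rowSums(sweep(z, 2, qnorm(d$alpha), "<")) == 4
  p_emp <- mean(hit)
  expect_lt(abs(p_emp - pairwise_error(d)$value),
            3 * sqrt(p_emp * (1 - p_emp) / n))
})

test_that("the pairwise error never exceeds any stagewise level", {
  for (d in list(stampede_design(), two_stage_design(), two_stage_design(alpha1 = 0.2),
                 calibrated_design(4, 2, 1))) {
    expect_lte(pairwise_error(d)$value, min(d$alpha))
  }
})

test_that("the maximum pairwise error equals the final-stage level for distinct outcomes", {
  expect_equal(max_pairwise_error(stampede_design())$value, 0.025)
  expect_equal(max_pairwise_error(two_stage_design())$value, 0.025)

  # identical outcomes: allowed only with non-binding boundaries
  d_id <- mams_design(2, 2, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                      control_events = c(72, 200), i_equals_d = TRUE,
                      binding = FALSE,
                      target_effect_I = log(0.75), target_effect_D = log(0.75))
  expect_equal(max_pairwise_error(d_id)$value, 0.025)
  d_bind <- mams_design(2, 2, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                        control_events = c(72, 200), i_equals_d = TRUE,
                        binding = TRUE,
                        target_effect_I = log(0.75), target_effect_D = log(0.75))
  expect_error(max_pairwise_error(d_bind), "global null")
})

test_that("the Dunnett maximum FWER matches a quadrature oracle and its bounds", {
  cases <- expand.grid(K = c(2, 3, 5), A = c(0.5, 1), aJ = c(0.01, 0.025))
  for (i in seq_len(nrow(cases))) {
    K <- cases$K[i]; A <- cases$A[i]; aJ <- cases$aJ[i]
    d <- mams_design(1, K, A, alpha = aJ, omega = 0.9, control_events = 100,
                     target_effect_I = log(0.75), target_effect_D = log(0.75))
    fw <- max_fwer(d)$value
    expect_equal(fw, dunnett_fwer_oracle(K, A, aJ), tolerance = 1e-6)
    # Dunnett bounds: alpha_J <= FWER <= 1-(1-alpha_J)^K <= K alpha_J
    expect_gte(fw, aJ)
    expect_lte(fw, 1 - (1 - aJ)^K)
    expect_lte(1 - (1 - aJ)^K, K * aJ)
  }
})

test_that("the maximum FWER increases with arms and level, decreases with shared-control correlation", {
  base <- function(K, A, aJ) {
    d <- mams_design(1, K, A, alpha = aJ, omega = 0.9, control_events = 100,
                     target_effect_I = log(0.75), target_effect_D = log(0.75))
    max_fwer(d)$value
  }
  expect_true(all(diff(sapply(1:6, base, A = 0.5, aJ = 0.025)) > 0))
  expect_true(all(diff(sapply(c(0.005, 0.01, 0.025, 0.05),
                              function(a) base(3, 1, a))) > 0))
  # raising A raises the between-arm correlation A/(A+1), pulling the
  # joint probability up and hence the familywise error down towards
  # its perfect-correlation limit alpha_J
  expect_true(all(diff(sapply(c(0.25, 0.5, 1, 2),
                              function(A) base(3, A, 0.025))) < 0))
})

test_that("an effect on the intermediate outcome inflates the PWER towards the plateau", {
  d <- two_stage_design()
  base <- pairwise_error(d)$value
  expect_equal(pwer_under_scenario(d, 0)$value, base)
  expect_equal(pwer_under_scenario(d, -Inf)$value, 0.025)

  grid <- c(0.1, 0, -0.1, -0.223, -0.7, -Inf)
  vals <- sapply(grid, function(th) pwer_under_scenario(d, th)$value)
  expect_true(all(diff(vals) >= 0))          # monotone as benefit grows
  expect_true(all(vals <= 0.025 + 1e-10))
  mid <- pwer_under_scenario(d, -0.2)$value
  expect_gt(mid, base)
  expect_lt(mid, 0.025)

  # cross-check the shifted orthant against trial simulation (single arm)
  d1 <- mams_design(2, 1, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
                    control_events = c(72, 200),
                    target_effect_I = log(0.75), target_effect_D = log(0.75))
  sim <- estimate_error_rates(d1, effect_scenario(d1, -0.2, 0),
                              n_reps = 4e5, seed = 77)
  p <- sim$pwer_per_arm[1]
  expect_lt(abs(p - pwer_under_scenario(d1, -0.2)$value),
            3 * sqrt(p * (1 - p) / sim$n_reps))
})

test_that("error-rate results carry their provenance", {
  r <- pairwise_error(stampede_design())
  expect_s3_class(r, "mams_error_rate")
  expect_identical(r$method, "analytic")
  expect_identical(r$mc_se, 0)
  expect_equal(as.numeric(r), r$value)
  expect_output(print(r), "pairwise type I error rate")
})
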