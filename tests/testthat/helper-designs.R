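# Fixture designs used across the test files.

# Six-arm four-stage time-to-event design: FFS at three interims, OS at the
# final analysis (Table-1-style inputs).
stampede_design <- function(binding = TRUE) {
  mams_design(
    n_stages = 4, n_arms = 5, allocation_ratio = 0.5,
    alpha = c(0.500, 0.250, 0.100, 0.025),
    omega = c(0.95, 0.95, 0.95, 0.90),
    control_events = c(113, 216, 334, 403),
    target_effect_I = log(0.75), target_effect_D = log(0.75),
    binding = binding
  )
}

# Two-stage three-arm fixture in the style of the published two-stage
# examples (first-stage level 0.5, final 0.025, equal allocation). The
# published examples do not state their event counts, so the interim
# information fraction is back-fitted: e = (72, 200) gives a between-stage
# correlation of sqrt(72/200) = 0.6.
two_stage_design <- function(K = 2, alpha1 = 0.5, binding = TRUE) {
  mams_design(
    n_stages = 2, n_arms = K, allocation_ratio = 1,
    alpha = c(alpha1, 0.025), omega = c(0.95, 0.90),
    control_events = c(72, 200),
    target_effect_I = log(0.75), target_effect_D = log(0.75),
    binding = binding
  )
}

# Design whose event counts are exactly Schoenfeld-calibrated to the
# stagewise (alpha_j, omega_j, target log HR, A): under the target effect
# the stagewise mean shift is -(z_{1-alpha_j} + z_{omega_j}), so the
# analytic power formula (alpha quantiles replaced by omega quantiles)
# holds exactly and can be compared against simulation.
calibrated_design <- function(J, K, A, hr = 0.75,
                              alpha = NULL, omega = NULL, binding = TRUE) {
  if (is.null(alpha))
    alpha <- switch(as.character(J),
                    "1" = 0.025,
                    "2" = c(0.5, 0.025),
                    "4" = c(0.5, 0.25, 0.1, 0.025),
                    rev(seq(0.025, 0.5, length.out = J)))
  if (is.null(omega)) omega <- rep(0.9, J)
  th <- log(hr)
  e <- (qnorm(1 - alpha) + qnorm(omega))^2 * (1 + A) / (A * th^2)
  mams_design(
    n_stages = J, n_arms = K, allocation_ratio = A,
    alpha = alpha, omega = omega, control_events = e,
    target_effect_I = th, target_effect_D = th,
    binding = binding
  )
}

# Independent oracle for the equicorrelated Dunnett probability:
# P(at least one of K shifted-null statistics exceeds z) computed by 1-D
# quadrature over the shared control factor.
dunnett_fwer_oracle <- function(K, A, alpha_J) {
  rho <- A / (A + 1)
  z <- qnorm(1 - alpha_J)
  f <- function(u) dnorm(u) * pnorm((z - sqrt(rho) * u) / sqrt(1 - rho))^K
  1 - integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
}

# Brute-force shared-control oracle: simulates the accumulating-information
# normal model at the "patient" level (unit-variance score increments for
# each control/experimental event) and returns the empirical correlation
# matrix of the stacked stagewise effect estimates (stage fastest, arm
# major), matching the layout of joint_corr().
shared_control_oracle <- function(design, n_reps, seed) {
  set.seed(seed)
  J <- design$n_stages; K <- design$n_arms
  e <- design$control_events; A <- design$allocation_ratio
  cum_norm <- function(n, counts) {
    # cumulative sums over nested event sets, returned as n x J means
    inc <- matrix(rnorm(n * length(counts)), n) *
      rep(sqrt(diff(c(0, counts))), each = n)
    if (length(counts) == 1L) return(inc / counts)
    t(apply(inc, 1L, cumsum)) / rep(counts, each = n)
  }
  ctrl <- cum_norm(n_reps, e)                  # control-arm mean estimates
  est <- vector("list", K)
  for (k in seq_len(K)) est[[k]] <- cum_norm(n_reps, A * e) - ctrl
  cor(do.call(cbind, est))
}
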