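#' Simulate the joint stagewise z-statistics of a MAMS trial
#'
#' Draws replicates of the full set of stagewise treatment-effect
#' z-statistics \eqn{Z_{jk}} (stage \eqn{j}, arm \eqn{k}) from the
#' \eqn{JK}-dimensional normal distribution with correlation
#' \code{\link{joint_corr}(design)} and mean \eqn{\mu_{jk} = (\theta_{jk} -
#' \theta_j^0)/SE_j}, where \eqn{\theta_{jk}} is the scenario's underlying
#' effect on the stage-\eqn{j} outcome (\eqn{\theta_{Ik}} at interims,
#' \eqn{\theta_{Dk}} at the final stage when the outcomes differ). This is
#' statistic-level simulation of the trial: no patient-level event times are
#' generated.
#'
#' Arms with \code{theta_I = -Inf} (or \code{+Inf}) are handled as sentinels:
#' their interim statistics are fixed at \code{-Inf} (\code{+Inf}) so the arm
#' passes (fails) every interim with probability one, while the final-stage
#' statistic is still drawn from its marginal model.
#'
#' @param design a \code{\link{mams_design}}.
#' @param scenario an \code{\link{effect_scenario}}; defaults to the global
#'   null.
#' @param n_reps number of Monte-Carlo replicates.
#' @param seed integer seed (required: results are reproducible by
#'   construction).
#' @return A numeric matrix with \code{n_reps} rows and \eqn{JK} columns
#'   named \code{Z<j>.<k>}, stage varying fastest within arm.
#' @examples
#' d <- mams_design(2, 2, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
#'                  control_events = c(72, 200),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' z <- simulate_trial_stats(d, null_scenario(d), n_reps = 1000, seed = 1)
#' cor(z[, "Z1.1"], z[, "Z2.1"])  # ~ sqrt(72/200)
#' @export
simulate_trial_stats <- function(design, scenario = null_scenario(design),
                                 n_reps, seed) {
  stopifnot(inherits(design, "mams_design"),
            inherits(scenario, "mams_scenario"))
  if (length(scenario$theta_I) != design$n_arms)
    stop("scenario does not match the design's number of arms", call. = FALSE)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be supplied as a single integer", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  J <- design$n_stages; K <- design$n_arms
  V <- joint_corr(design)
  # eigen square root: tolerant of the semi-definite matrices produced by
  # tied event counts (perfect between-stage correlation)
  eg <- eigen(V, symmetric = TRUE)
  rt <- eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
  mu <- mean_matrix(design, scenario)          # J x K, may contain +/-Inf
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_reps * J * K), nrow = n_reps) %*% rt
  z <- sweep(z, 2L, as.vector(mu), "+")        # columns ordered arm-major
  colnames(z) <- paste0("Z", rep(seq_len(J), K), ".", rep(seq_len(K), each = J))
  z
}

# J x K matrix of mean shifts mu_jk; sentinel infinities preserved
mean_matrix <- function(design, scenario) {
  J <- design$n_stages; K <- design$n_arms
  se <- stage_se(design)
  mu <- matrix(0, J, K)
  for (k in seq_len(K)) {
    th_I <- scenario$theta_I[k]
    th_D <- scenario$theta_D[k]
    if (design$i_equals_d) {
      mu[, k] <- (th_D - design$null_effect_D) / se
    } else {
      if (J > 1)
        mu[-J, k] <- if (is.infinite(th_I)) th_I else
          (th_I - design$null_effect_I) / se[-J]
      mu[J, k] <- (th_D - design$null_effect_D) / se[J]
    }
  }
  mu
}

#' Monte-Carlo operating characteristics under an effect scenario
#'
#' Simulates the trial (\code{\link{simulate_trial_stats}}) and applies the
#' stopping and decision rules: an arm records a rejection in a replicate
#' when it passes all interim thresholds (\eqn{Z_{jk} <
#' \Phi^{-1}(\alpha_j)}, required only when the design's boundaries are
#' binding) and its final-stage statistic is significant at
#' \eqn{\alpha_J}. With non-binding boundaries all arms reach the final
#' stage, the configuration that maximises the error rates.
#'
#' A rejection counts towards the type I error rates for arms whose true
#' definitive-outcome effect is at or above the null (the null hypothesis on
#' D is true), and towards power for arms at or below the design's target
#' effect.
#'
#' @inheritParams simulate_trial_stats
#' @return An object of class \code{"mams_sim"}: a list with
#'   \code{reject_per_arm} (rejection frequency, all arms),
#'   \code{pwer_per_arm} (rejection frequency for null-true arms, else
#'   \code{NA}), \code{power_per_arm} (for arms at/below the target effect,
#'   else \code{NA}), \code{fwer} (frequency of at least one false
#'   rejection), \code{mc_se_fwer}, \code{n_reps}, \code{seed}.
#' @examples
#' d <- mams_design(2, 2, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
#'                  control_events = c(72, 200),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' estimate_error_rates(d, effect_scenario(d, -Inf, 0),
#'                      n_reps = 1e4, seed = 42)
#' @export
estimate_error_rates <- function(design, scenario = null_scenario(design),
                                 n_reps = 250000, seed) {
  stopifnot(inherits(design, "mams_design"))
  z <- simulate_trial_stats(design, scenario, n_reps = n_reps, seed = seed)
  J <- design$n_stages; K <- design$n_arms
  crit <- stats::qnorm(design$alpha)
  reject <- matrix(FALSE, nrow(z), K)
  for (k in seq_len(K)) {
    cols <- (k - 1L) * J + seq_len(J)
    zk <- z[, cols, drop = FALSE]
    final_sig <- zk[, J] < crit[J]
    if (design$binding && J > 1) {
      pass <- rep(TRUE, nrow(z))
      for (j in seq_len(J - 1L)) pass <- pass & (zk[, j] < crit[j])
      reject[, k] <- pass & final_sig
    } else {
      reject[, k] <- final_sig
    }
  }
  null_true <- scenario$theta_D >= design$null_effect_D
  at_target <- scenario$theta_D <= design$target_effect_D
  rate <- colMeans(reject)
  fw <- if (any(null_true))
    mean(apply(reject[, null_true, drop = FALSE], 1L, any)) else NA_real_
  structure(list(
    reject_per_arm = rate,
    pwer_per_arm = ifelse(null_true, rate, NA_real_),
    power_per_arm = ifelse(at_target, rate, NA_real_),
    fwer = fw,
    mc_se_fwer = if (is.na(fw)) NA_real_ else sqrt(fw * (1 - fw) / n_reps),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed)
  ), class = "mams_sim")
}

#' @export
print.mams_sim <- function(x, ...) {
  cat(sprintf("MAMS simulation (%d replicates, seed %d)\n", x$n_reps, x$seed))
  print(data.frame(arm = seq_along(x$reject_per_arm),
                   reject = x$reject_per_arm,
                   pwer = x$pwer_per_arm,
                   power = x$power_per_arm),
        row.names = FALSE, digits = 4)
  if (!is.na(x$fwer))
    cat(sprintf("FWER (null-true arms): %.4f (MC se %.2e)\n",
                x$fwer, x$mc_se_fwer))
  invisible(x)
}

#' @rdname estimate_error_rates
#' @param object a \code{\link{mams_design}}.
#' @param nsim number of Monte-Carlo replicates.
#' @param ... passed on (unused).
#' @details \code{simulate} is the S3 method interface to
#'   \code{estimate_error_rates}: \code{simulate(design, nsim, seed,
#'   scenario = ...)}.
#' @export
simulate.mams_design <- function(object, nsim = 250000, seed = NULL,
                                 scenario = null_scenario(object), ...) {
  if (is.null(seed)) stop("`seed` must be supplied", call. = FALSE)
  estimate_error_rates(object, scenario, n_reps = nsim, seed = seed)
}

#' Sweep the intermediate-outcome effect and record the error rates
#'
#' Re-evaluates the simulated operating characteristics over a grid of
#' underlying log hazard ratios on the intermediate outcome, applied to a
#' chosen subset of arms (the rest stay at the null on I); the definitive
#' outcome is held at the null throughout, so every rejection is a type I
#' error. All grid points reuse the same seed, so comparisons along the grid
#' are coupled.
#'
#' @param design a \code{\link{mams_design}}.
#' @param theta_I_grid numeric vector of log hazard ratios (may include
#'   \code{-Inf}).
#' @param which_arms integer indices of the arms whose effect on I varies
#'   (default: all arms).
#' @param n_reps,seed Monte-Carlo control as in
#'   \code{\link{estimate_error_rates}}.
#' @return A data frame of class \code{"mams_sweep"} with columns
#'   \code{theta_I}, \code{hr_I}, \code{pwer} (first varied arm),
#'   \code{fwer}, \code{mc_se_fwer}, \code{n_reps}, \code{seed}.
#' @examples
#' d <- mams_design(2, 2, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
#'                  control_events = c(72, 200),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' sw <- scenario_sweep(d, c(0, log(0.8), -Inf), n_reps = 1e4, seed = 7)
#' sw
#' @export
scenario_sweep <- function(design, theta_I_grid, which_arms = seq_len(design$n_arms),
                           n_reps = 250000, seed) {
  stopifnot(inherits(design, "mams_design"))
  if (length(theta_I_grid) == 0L) stop("`theta_I_grid` is empty", call. = FALSE)
  which_arms <- as.integer(which_arms)
  if (length(which_arms) == 0L || any(which_arms < 1) ||
      any(which_arms > design$n_arms))
    stop("`which_arms` must index experimental arms of the design",
         call. = FALSE)
  rows <- lapply(theta_I_grid, function(th) {
    theta_I <- rep(design$null_effect_I, design$n_arms)
    theta_I[which_arms] <- th
    sc <- effect_scenario(design, theta_I, design$null_effect_D)
    sim <- estimate_error_rates(design, sc, n_reps = n_reps, seed = seed)
    data.frame(theta_I = th, hr_I = exp(th),
               pwer = sim$pwer_per_arm[which_arms[1L]],
               fwer = sim$fwer, mc_se_fwer = sim$mc_se_fwer,
               n_reps = sim$n_reps, seed = sim$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mams_sweep", "data.frame")
  out
}

#' @export
plot.mams_sweep <- function(x, which = c("fwer", "pwer"), ...) {
  which <- match.arg(which)
  th <- x$theta_I
  finite <- is.finite(th)
  xx <- th
  if (any(!finite)) # place -Inf just beyond the finite range for display
    xx[!finite] <- min(th[finite], 0) - 0.25 * diff(range(th[finite], 0))
  ord <- order(xx)
  plot(xx[ord], x[[which]][ord], type = "b", pch = 16,
       xlab = expression(theta[I] ~ "(log hazard ratio on I)"),
       ylab = toupper(which), ...)
  invisible(x)
}
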