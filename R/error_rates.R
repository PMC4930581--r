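#' @title Analytic operating characteristics of a MAMS design
#'
#' @description
#' These functions evaluate a design's type I error rates and power from
#' multivariate-normal orthant probabilities, without simulation.
#'
#' \code{pairwise_error} computes the pairwise type I error rate (PWER) under
#' the joint null on both outcomes,
#' \deqn{\alpha = \Phi_J(z_{\alpha_1}, \dots, z_{\alpha_J}; R),}
#' the probability that one experimental arm with no effect on I or D passes
#' every interim threshold and is significant at the final stage. \eqn{R} is
#' the between-stage correlation matrix and \eqn{z_{\alpha_j} =
#' \Phi^{-1}(\alpha_j)} (benefit is a negative z-statistic, so passage is a
#' lower-tail event).
#'
#' \code{pairwise_power} is the same orthant probability with the stagewise
#' significance levels replaced by the stagewise powers \eqn{\omega_j}.
#'
#' \code{max_pairwise_error} returns the maximum PWER over all possible true
#' effects on the intermediate outcome. An arm that is extremely effective on
#' I but null on D passes every interim with probability one, so the interim
#' stages become redundant and the maximum equals the final-stage level
#' \eqn{\alpha_J}. This holds for designs with distinct outcomes, and for
#' identical outcomes when the boundaries are non-binding; for identical
#' outcomes with binding boundaries the maximum occurs at the global null
#' and is the \code{pairwise_error} value instead, so the function refuses.
#'
#' \code{max_fwer} computes the maximum familywise error rate via the Dunnett
#' many-to-one probability
#' \deqn{\mathrm{FWER} = 1 - \Phi_K(z_{1-\alpha_J}, \dots, z_{1-\alpha_J}; C),}
#' where \eqn{C} has off-diagonal entries \eqn{A/(A+1)}. The maximising
#' scenario (all arms pass all interims, all null on D) reduces the trial to
#' a single-stage many-to-one comparison at level \eqn{\alpha_J}.
#'
#' \code{pwer_under_scenario} gives the PWER of a single arm whose true
#' intermediate-outcome effect is \code{theta_I} (definitive outcome at the
#' null): interim coordinates are shifted by \eqn{(\theta_I -
#' \theta_I^0)/SE_j} with \eqn{SE_j = \sqrt{(1+A)/(A e_j)}}, the final
#' coordinate is unshifted. It interpolates between \code{pairwise_error}
#' (at the null) and \eqn{\alpha_J} (as \eqn{\theta_I \to -\infty}).
#'
#' @param design a \code{\link{mams_design}}.
#' @param theta_I a single underlying log hazard ratio on the intermediate
#'   outcome (\code{-Inf} allowed).
#' @return An object of class \code{"mams_error_rate"}: a list with
#'   \code{value}, \code{kind} (\code{"pwer"}, \code{"power"} or
#'   \code{"fwer"}), \code{method} (\code{"analytic"}), \code{mc_se} (0),
#'   \code{n_reps} (0).
#' @examples
#' d <- mams_design(4, 5, 0.5, alpha = c(0.5, 0.25, 0.1, 0.025),
#'                  omega = c(0.95, 0.95, 0.95, 0.9),
#'                  control_events = c(113, 216, 334, 403),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' pairwise_error(d)
#' max_fwer(d)        # Dunnett probability, K = 5, correlation 1/3
#' @name error_rates
NULL

error_rate_result <- function(value, kind, method = "analytic",
                              mc_se = 0, n_reps = 0L, seed = NULL) {
  stopifnot(value >= 0, value <= 1 + 1e-12)
  structure(list(value = min(as.numeric(value), 1),
                 kind = kind, method = method,
                 mc_se = mc_se, n_reps = n_reps, seed = seed),
            class = "mams_error_rate")
}

#' @export
print.mams_error_rate <- function(x, ...) {
  lab <- c(pwer = "pairwise type I error rate",
           power = "overall pairwise power",
           fwer = "familywise error rate")[x$kind]
  cat(sprintf("%s: %.4f (%s", lab, x$value, x$method))
  if (x$method == "simulation")
    cat(sprintf(", %d replicates, MC se %.2e, seed %s",
                x$n_reps, x$mc_se,
                if (is.null(x$seed)) "unset" else format(x$seed)))
  cat(")\n")
  invisible(x)
}

#' @export
as.double.mams_error_rate <- function(x, ...) x$value

#' @rdname error_rates
#' @export
pairwise_error <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  R <- between_stage_corr(design)
  error_rate_result(mvn_lower(stats::qnorm(design$alpha), R), "pwer")
}

#' @rdname error_rates
#' @export
pairwise_power <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  R <- between_stage_corr(design)
  error_rate_result(mvn_lower(stats::qnorm(design$omega), R), "power")
}

#' @rdname error_rates
#' @export
max_pairwise_error <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  if (design$i_equals_d && design$binding)
    stop(paste("with identical interim and final outcomes and binding",
               "boundaries the maximum PWER occurs at the global null and",
               "equals pairwise_error(design); control through the",
               "final-stage level alone does not apply"), call. = FALSE)
  error_rate_result(design$alpha[design$n_stages], "pwer")
}

#' @rdname error_rates
#' @export
max_fwer <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  error_rate_result(
    dunnett_fwer(design$n_arms, design$allocation_ratio,
                 design$alpha[design$n_stages]),
    "fwer")
}

# Dunnett many-to-one maximum FWER at final-stage level alpha_J
dunnett_fwer <- function(K, A, alpha_J) {
  C <- between_arm_corr(K, A)
  1 - mvn_lower(rep(stats::qnorm(1 - alpha_J), K), C)
}

#' @rdname error_rates
#' @export
pwer_under_scenario <- function(design, theta_I) {
  stopifnot(inherits(design, "mams_design"))
  if (length(theta_I) != 1L || is.na(theta_I))
    stop("`theta_I` must be a single log hazard ratio (possibly -Inf)",
         call. = FALSE)
  J <- design$n_stages
  upper <- stats::qnorm(design$alpha)
  if (J > 1) {
    shift <- (theta_I - design$null_effect_I) / stage_se(design)[-J]
    # -Inf effect: interims passed surely -> coordinate +Inf (dropped)
    upper[-J] <- ifelse(shift == -Inf, Inf, upper[-J] - shift)
  }
  R <- between_stage_corr(design)
  error_rate_result(mvn_lower(upper, R), "pwer")
}
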