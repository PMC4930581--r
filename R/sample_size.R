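#' Approximate control-arm events for a pairwise stage comparison
#'
#' Schoenfeld-type event requirement for a one-sided log-rank comparison of
#' one experimental arm against control at level \eqn{\alpha_j} with power
#' \eqn{\omega_j} to detect a target log hazard ratio \eqn{\theta}:
#' \deqn{e_C = \left\lceil (z_{1-\alpha_j} + z_{\omega_j})^2 \,
#'   \frac{1+A}{A\,\theta^2} \right\rceil,}
#' the control-arm share of events when \eqn{A} patients are allocated to
#' the experimental arm per control patient. This closed form is an
#' approximation: dedicated design software uses a different internal
#' algorithm and its published event counts differ by a few percent (for
#' example, 403 rather than 381 for a final stage at \eqn{\alpha = 0.025},
#' \eqn{\omega = 0.9}, hazard ratio 0.75, \eqn{A = 0.5}). Error-rate
#' computations in this package take event counts as inputs, so the
#' approximation never propagates into them.
#'
#' @param alpha_j one-sided significance level in (0, 1).
#' @param omega_j power in (0, 1).
#' @param target_log_hr negative target log hazard ratio.
#' @param A positive allocation ratio.
#' @return Integer number of control-arm events.
#' @examples
#' control_events_for_stage(0.025, 0.90, log(0.75), A = 0.5)
#' @export
control_events_for_stage <- function(alpha_j, omega_j, target_log_hr, A) {
  if (alpha_j <= 0 || alpha_j >= 1 || omega_j <= 0 || omega_j >= 1)
    stop("`alpha_j` and `omega_j` must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(target_log_hr) || target_log_hr >= 0)
    stop("`target_log_hr` must be a negative log hazard ratio (no detectable difference at 0)",
         call. = FALSE)
  if (!is.finite(A) || A <= 0)
    stop("`A` must be a positive allocation ratio", call. = FALSE)
  zsum <- stats::qnorm(1 - alpha_j) + stats::qnorm(omega_j)
  if (zsum <= 0)
    stop("degenerate requirement: z_{1-alpha} + z_{omega} must be positive",
         call. = FALSE)
  as.integer(ceiling(zsum^2 * (1 + A) / (A * target_log_hr^2)))
}

#' Re-plan the final stage after tightening its significance level
#'
#' When the final-stage level is reduced (for example to control the
#' familywise error rate in the strong sense), the final-stage event
#' requirement grows. The original final-stage count is rescaled by the
#' squared ratio of normal-quantile sums,
#' \deqn{e_J' = \left\lceil e_J \left( \frac{z_{1-\alpha_J'} +
#'   z_{\omega_J}}{z_{1-\alpha_J} + z_{\omega_J}} \right)^2 \right\rceil,}
#' which preserves whatever internal calibration produced the original
#' count. Earlier stages are unchanged.
#'
#' @param design a \code{\link{mams_design}}.
#' @param new_alpha_J replacement final-stage level, in (0, current
#'   \eqn{\alpha_J}].
#' @return A new \code{\link{mams_design}} with the final-stage level and
#'   event count updated.
#' @examples
#' d <- mams_design(4, 5, 0.5, alpha = c(0.5, 0.25, 0.1, 0.025),
#'                  omega = c(0.95, 0.95, 0.95, 0.9),
#'                  control_events = c(113, 216, 334, 403),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' redesign_final_stage(d, 0.0054)$control_events[4]
#' @export
redesign_final_stage <- function(design, new_alpha_J) {
  stopifnot(inherits(design, "mams_design"))
  J <- design$n_stages
  old <- design$alpha[J]
  if (length(new_alpha_J) != 1L || !is.finite(new_alpha_J) ||
      new_alpha_J <= 0 || new_alpha_J > old)
    stop(sprintf("`new_alpha_J` must lie in (0, %g], the current final-stage level",
                 old), call. = FALSE)
  zw <- stats::qnorm(design$omega[J])
  ratio <- (stats::qnorm(1 - new_alpha_J) + zw) / (stats::qnorm(1 - old) + zw)
  out <- design
  out$alpha[J] <- new_alpha_J
  out$control_events[J] <- ceiling(design$control_events[J] * ratio^2)
  out
}
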