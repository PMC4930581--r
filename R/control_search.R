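#' Final-stage significance level for strong familywise error control
#'
#' Finds the final-stage one-sided level \eqn{\alpha_J} at which the
#' \emph{maximum} familywise error rate of the design — attained when every
#' arm is certain to pass the interims but null on the definitive outcome —
#' equals the target. Since the maximum FWER is the single-stage Dunnett
#' probability \eqn{1 - \Phi_K(z_{1-\alpha_J}, \dots; C)}, only \eqn{K}, the
#' allocation ratio and \eqn{\alpha_J} matter.
#'
#' Two search methods are provided. \code{"grid"} replicates the published
#' search exactly: candidate levels run from the Bonferroni bound
#' \eqn{\mathrm{target}/K} up to the target in steps of 0.0001, and the
#' largest level whose maximum FWER does not exceed the target is returned.
#' A level whose FWER ties with the target at the grid's own precision
#' (within half a unit in the fourth decimal place, 5e-5) counts as not
#' exceeding it, which matches the published search where achieved rates
#' were compared at four decimal places. \code{"quantile"} solves the
#' equicoordinate equation for \eqn{z} by root finding, converts with
#' \eqn{\alpha_J = 1 - \Phi(z)}, and rounds down to four decimal places for
#' comparability with the grid; the two methods agree to within one grid
#' step.
#'
#' @param design a \code{\link{mams_design}}.
#' @param target_fwer one-sided familywise error target in (0, 1).
#' @param method \code{"grid"} (default) or \code{"quantile"}.
#' @return The selected final-stage significance level (a probability,
#'   rounded to four decimal places), with attributes \code{achieved_fwer}
#'   and \code{method}.
#' @examples
#' d <- mams_design(4, 5, 0.5, alpha = c(0.5, 0.25, 0.1, 0.025),
#'                  omega = c(0.95, 0.95, 0.95, 0.9),
#'                  control_events = c(113, 216, 334, 403),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' find_alpha_J_for_fwer(d, 0.025)   # 0.0054
#' find_alpha_J_for_fwer(d, 0.05)    # 0.0113
#' @export
find_alpha_J_for_fwer <- function(design, target_fwer,
                                  method = c("grid", "quantile")) {
  stopifnot(inherits(design, "mams_design"))
  method <- match.arg(method)
  if (length(target_fwer) != 1L || !is.finite(target_fwer) ||
      target_fwer <= 0 || target_fwer >= 1)
    stop("`target_fwer` must lie strictly in (0, 1)", call. = FALSE)
  K <- design$n_arms
  A <- design$allocation_ratio
  if (method == "grid") {
    step <- 1e-4
    # Bonferroni bound target/K is always feasible; grid runs up to target
    lo <- ceiling(target_fwer / K / step) * step
    grid <- seq(lo, target_fwer, by = step)
    if (length(grid) == 0L)
      stop("target too small for the 0.0001 search grid", call. = FALSE)
    fw <- vapply(grid, function(a) dunnett_fwer(K, A, a), numeric(1))
    ok <- fw <= target_fwer + 5e-5   # ties at 4-dp precision count as met
    if (!any(ok))
      stop("no grid level meets the target familywise error rate",
           call. = FALSE)
    i <- max(which(ok))
    out <- round(grid[i], 4)
    attr(out, "achieved_fwer") <- fw[i]
  } else {
    z <- stats::uniroot(
      function(z) dunnett_fwer_z(K, A, z) - target_fwer,
      lower = stats::qnorm(1 - target_fwer) - 1e-9,
      upper = stats::qnorm(1 - target_fwer / K) + 1e-9,
      tol = 1e-10
    )$root
    out <- floor((1 - stats::pnorm(z)) * 1e4) / 1e4
    attr(out, "achieved_fwer") <- dunnett_fwer(K, A, out)
  }
  attr(out, "method") <- method
  out
}

# FWER as a function of the common upper quantile z
dunnett_fwer_z <- function(K, A, z) {
  1 - mvn_lower(rep(z, K), between_arm_corr(K, A))
}

#' Final-stage significance level for strong pairwise error control
#'
#' For designs whose interim and final outcomes differ (or coincide with
#' non-binding boundaries), the maximum pairwise type I error rate equals
#' the final-stage level, so strong control at \eqn{\alpha^*} is achieved by
#' setting \eqn{\alpha_J = \alpha^*}. For identical outcomes with binding
#' boundaries every stagewise level contributes to the maximum and a joint
#' search would be needed; the function refuses in that case.
#'
#' @param design a \code{\link{mams_design}}.
#' @param target_pwer desired maximum pairwise type I error rate in (0, 1).
#' @return The required final-stage significance level (equal to
#'   \code{target_pwer}).
#' @export
find_alpha_J_for_pwer <- function(design, target_pwer) {
  stopifnot(inherits(design, "mams_design"))
  if (length(target_pwer) != 1L || !is.finite(target_pwer) ||
      target_pwer <= 0 || target_pwer >= 1)
    stop("`target_pwer` must lie strictly in (0, 1)", call. = FALSE)
  if (design$i_equals_d && design$binding)
    stop(paste("strong pairwise error control through the final-stage level",
               "alone applies only when the outcomes differ or the",
               "boundaries are non-binding; with identical outcomes and",
               "binding boundaries all stagewise levels contribute"),
         call. = FALSE)
  target_pwer
}
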