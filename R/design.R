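#' Specify a multi-arm multi-stage (MAMS) trial design
#'
#' Constructs and validates the static description of a MAMS trial in which
#' \code{K} experimental arms are compared against a shared control over at
#' most \code{J} stages. Interim analyses (stages \eqn{1, \dots, J-1}) test an
#' intermediate outcome \emph{I}; the final stage tests the definitive outcome
#' \emph{D}. Treatment effects are log hazard ratios with the convention that
#' negative values denote benefit, so an arm passes stage \eqn{j} when its
#' one-sided z-statistic falls below \eqn{\Phi^{-1}(\alpha_j)}.
#'
#' The timing of each stage-\eqn{j} analysis is indexed by the cumulative
#' number of control-arm events \code{control_events[j]}; these determine the
#' information fractions and hence the between-stage correlation of the
#' stagewise treatment-effect estimates (see \code{\link{between_stage_corr}}).
#'
#' @param n_stages integer, number of stages \eqn{J \ge 1}.
#' @param n_arms integer, number of experimental arms \eqn{K \ge 1}
#'   (control excluded).
#' @param allocation_ratio positive scalar \eqn{A}: patients allocated to each
#'   experimental arm per control patient (\eqn{A = 1} is equal allocation).
#' @param alpha numeric vector of length \code{n_stages}: one-sided stagewise
#'   significance levels \eqn{\alpha_j}, each in (0, 1).
#' @param omega numeric vector of length \code{n_stages}: stagewise powers
#'   \eqn{\omega_j}, each in (0, 1).
#' @param control_events positive, non-decreasing numeric vector of length
#'   \code{n_stages}: cumulative control-arm event counts \eqn{e_j} required
#'   to trigger each stage analysis.
#' @param target_effect_I,target_effect_D target (alternative) log hazard
#'   ratios on the intermediate and definitive outcomes; must lie below the
#'   corresponding null effects.
#' @param null_effect_I,null_effect_D null log hazard ratios (default 0,
#'   i.e. hazard ratio 1).
#' @param i_equals_d logical; \code{TRUE} when the intermediate and definitive
#'   outcomes coincide (all stages test the same outcome).
#' @param binding logical; whether the interim stopping boundaries are
#'   binding. With non-binding boundaries an arm may continue past a failed
#'   interim without inflating the maximum error rates controlled by the
#'   final-stage level.
#'
#' @return An object of class \code{"mams_design"}: a list with the validated
#'   fields above.
#'
#' @examples
#' # A six-arm four-stage design: failure-free survival at interims,
#' # overall survival at the final analysis, target hazard ratio 0.75.
#' d <- mams_design(
#'   n_stages = 4, n_arms = 5, allocation_ratio = 0.5,
#'   alpha = c(0.5, 0.25, 0.1, 0.025),
#'   omega = c(0.95, 0.95, 0.95, 0.90),
#'   control_events = c(113, 216, 334, 403),
#'   target_effect_I = log(0.75), target_effect_D = log(0.75)
#' )
#' d
#' @seealso \code{\link{summary.mams_design}} for the analytic operating
#'   characteristics, \code{\link{simulate.mams_design}} for Monte-Carlo
#'   evaluation, \code{\link{read_mams_config}} for file-based specification.
#' @export
mams_design <- function(n_stages, n_arms, allocation_ratio,
                        alpha, omega, control_events,
                        target_effect_I, target_effect_D,
                        null_effect_I = 0, null_effect_D = 0,
                        i_equals_d = FALSE, binding = TRUE) {
  if (length(n_stages) != 1L || !is.finite(n_stages) || n_stages < 1 ||
      n_stages != round(n_stages))
    stop("`n_stages` must be a single integer >= 1", call. = FALSE)
  if (length(n_arms) != 1L || !is.finite(n_arms) || n_arms < 1 ||
      n_arms != round(n_arms))
    stop("`n_arms` must be a single integer >= 1", call. = FALSE)
  n_stages <- as.integer(n_stages)
  n_arms <- as.integer(n_arms)
  if (length(allocation_ratio) != 1L || !is.finite(allocation_ratio) ||
      allocation_ratio <= 0)
    stop("`allocation_ratio` must be a single positive number", call. = FALSE)
  if (length(alpha) != n_stages)
    stop("`alpha` must have length n_stages (one level per stage)",
         call. = FALSE)
  if (length(omega) != n_stages)
    stop("`omega` must have length n_stages (one power per stage)",
         call. = FALSE)
  if (length(control_events) != n_stages)
    stop("`control_events` must have length n_stages", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1))
    stop("all stagewise significance levels `alpha` must lie strictly in (0, 1)",
         call. = FALSE)
  if (any(!is.finite(omega)) || any(omega <= 0) || any(omega >= 1))
    stop("all stagewise powers `omega` must lie strictly in (0, 1)",
         call. = FALSE)
  if (any(!is.finite(control_events)) || any(control_events <= 0))
    stop("`control_events` must be strictly positive", call. = FALSE)
  if (n_stages > 1 && any(diff(control_events) < 0))
    stop("`control_events` must be non-decreasing across stages", call. = FALSE)
  for (nm in c("null_effect_I", "null_effect_D",
               "target_effect_I", "target_effect_D")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite log hazard ratio", nm),
           call. = FALSE)
  }
  if (target_effect_I >= null_effect_I)
    stop("`target_effect_I` must lie below `null_effect_I` (negative log HR = benefit)",
         call. = FALSE)
  if (target_effect_D >= null_effect_D)
    stop("`target_effect_D` must lie below `null_effect_D` (negative log HR = benefit)",
         call. = FALSE)
  if (!is.logical(i_equals_d) || length(i_equals_d) != 1L || is.na(i_equals_d))
    stop("`i_equals_d` must be TRUE or FALSE", call. = FALSE)
  if (!is.logical(binding) || length(binding) != 1L || is.na(binding))
    stop("`binding` must be TRUE or FALSE", call. = FALSE)

  structure(
    list(
      n_stages = n_stages,
      n_arms = n_arms,
      allocation_ratio = allocation_ratio,
      alpha = as.numeric(alpha),
      omega = as.numeric(omega),
      control_events = as.numeric(control_events),
      null_effect_I = null_effect_I,
      null_effect_D = null_effect_D,
      target_effect_I = target_effect_I,
      target_effect_D = target_effect_D,
      i_equals_d = i_equals_d,
      binding = binding
    ),
    class = "mams_design"
  )
}

#' @export
print.mams_design <- function(x, ...) {
  cat(sprintf("MAMS design: %d experimental arm%s vs control, %d stage%s\n",
              x$n_arms, if (x$n_arms > 1) "s" else "",
              x$n_stages, if (x$n_stages > 1) "s" else ""))
  cat(sprintf("  allocation ratio A = %g (between-arm correlation %.4f)\n",
              x$allocation_ratio,
              x$allocation_ratio / (x$allocation_ratio + 1)))
  cat(sprintf("  outcomes: %s; boundaries %s\n",
              if (x$i_equals_d) "I = D" else "intermediate (I) then definitive (D)",
              if (x$binding) "binding" else "non-binding"))
  tab <- data.frame(
    stage = seq_len(x$n_stages),
    alpha = x$alpha,
    omega = x$omega,
    control_events = x$control_events
  )
  print(tab, row.names = FALSE)
  cat(sprintf("  target log HR: I %.4f (HR %.3f), D %.4f (HR %.3f)\n",
              x$target_effect_I, exp(x$target_effect_I),
              x$target_effect_D, exp(x$target_effect_D)))
  invisible(x)
}

# stagewise standard error of the log-HR estimate:
# var = 1/e_C + 1/e_E with e_E ~ A * e_C under the null
stage_se <- function(design) {
  A <- design$allocation_ratio
  sqrt((1 + A) / (A * design$control_events))
}

#' Define an effect scenario for a MAMS design
#'
#' An effect scenario fixes the underlying (true) log hazard ratios of every
#' experimental arm on the intermediate and definitive outcomes. Operating
#' characteristics (type I error rates, power) are evaluated under a
#' scenario. \code{-Inf} is admissible for \code{theta_I}: such an arm is so
#' effective on the intermediate outcome that it passes every interim
#' analysis with probability one (the limiting configuration that maximises
#' the error rates); \code{+Inf} means the arm never passes an interim.
#'
#' @param design a \code{\link{mams_design}}.
#' @param theta_I,theta_D numeric vectors of per-arm underlying log hazard
#'   ratios on I and D; scalars are recycled to \code{design$n_arms}.
#' @return An object of class \code{"mams_scenario"} with elements
#'   \code{theta_I} and \code{theta_D}, each of length \code{design$n_arms}.
#' @examples
#' d <- mams_design(2, 2, 1, alpha = c(0.5, 0.025), omega = c(0.95, 0.9),
#'                  control_events = c(72, 200),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' effect_scenario(d, theta_I = -Inf, theta_D = 0)  # maximises the FWER
#' @export
effect_scenario <- function(design, theta_I, theta_D) {
  stopifnot(inherits(design, "mams_design"))
  K <- design$n_arms
  if (length(theta_I) == 1L) theta_I <- rep(theta_I, K)
  if (length(theta_D) == 1L) theta_D <- rep(theta_D, K)
  if (length(theta_I) != K || length(theta_D) != K)
    stop("`theta_I` and `theta_D` must have one entry per experimental arm",
         call. = FALSE)
  if (any(is.na(theta_I)) || any(is.na(theta_D)))
    stop("scenario effects must not be NA", call. = FALSE)
  if (any(!is.finite(theta_D)) && any(theta_D == -Inf))
    stop("`theta_D` must be finite or +Inf; -Inf is only meaningful on I",
         call. = FALSE)
  structure(list(theta_I = as.numeric(theta_I),
                 theta_D = as.numeric(theta_D)),
            class = "mams_scenario")
}

#' Global-null effect scenario
#'
#' Convenience constructor for the scenario in which every experimental arm
#' sits exactly at the null effect on both outcomes.
#'
#' @param design a \code{\link{mams_design}}.
#' @return A \code{\link{effect_scenario}} with all \code{theta_I} equal to
#'   the design's null effect on I and all \code{theta_D} equal to the null
#'   effect on D.
#' @export
null_scenario <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  effect_scenario(design,
                  theta_I = design$null_effect_I,
                  theta_D = design$null_effect_D)
}

#' @export
print.mams_scenario <- function(x, ...) {
  cat("Effect scenario (log hazard ratios):\n")
  print(data.frame(arm = seq_along(x$theta_I),
                   theta_I = x$theta_I, theta_D = x$theta_D),
        row.names = FALSE)
  invisible(x)
}

#' Read or write a MAMS design configuration file
#'
#' Designs are stored as YAML with keys mirroring the arguments of
#' \code{\link{mams_design}}. Effects are given under an \code{effects} block
#' whose \code{scale} key is either \code{"hr"} (natural hazard-ratio scale,
#' converted with the natural logarithm) or \code{"log_hr"}.
#'
#' @param path file path of the YAML configuration.
#' @return \code{read_mams_config} returns a validated
#'   \code{\link{mams_design}}; \code{write_mams_config} invisibly returns
#'   \code{path}.
#' @examples
#' cfg <- system.file("extdata", "stampede.yaml", package = "mamsio")
#' read_mams_config(cfg)
#' @export
read_mams_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design))
    stop("config must contain a top-level `design:` block", call. = FALSE)
  d <- cfg$design
  eff <- d$effects
  if (is.null(eff) || is.null(eff$scale))
    stop("config `design:` needs an `effects:` block with a `scale:` key ('hr' or 'log_hr')",
         call. = FALSE)
  to_log <- switch(as.character(eff$scale),
                   hr = function(v) log(as.numeric(v)),
                   log_hr = function(v) as.numeric(v),
                   stop("effects scale must be 'hr' or 'log_hr'", call. = FALSE))
  need <- function(val, key) {
    if (is.null(val)) stop(sprintf("config is missing `%s`", key), call. = FALSE)
    val
  }
  mams_design(
    n_stages = need(d$n_stages, "n_stages"),
    n_arms = need(d$n_arms, "n_arms"),
    allocation_ratio = need(d$allocation_ratio, "allocation_ratio"),
    alpha = as.numeric(unlist(need(d$alpha, "alpha"))),
    omega = as.numeric(unlist(need(d$omega, "omega"))),
    control_events = as.numeric(unlist(need(d$control_events, "control_events"))),
    target_effect_I = to_log(need(eff$target_I, "effects$target_I")),
    target_effect_D = to_log(need(eff$target_D, "effects$target_D")),
    null_effect_I = if (is.null(eff$null_I)) 0 else to_log(eff$null_I),
    null_effect_D = if (is.null(eff$null_D)) 0 else to_log(eff$null_D),
    i_equals_d = isTRUE(d$i_equals_d),
    binding = if (is.null(d$binding)) TRUE else isTRUE(d$binding)
  )
}

#' @rdname read_mams_config
#' @param design a \code{\link{mams_design}} to serialize.
#' @export
write_mams_config <- function(design, path) {
  stopifnot(inherits(design, "mams_design"))
  cfg <- list(design = list(
    n_stages = design$n_stages,
    n_arms = design$n_arms,
    allocation_ratio = design$allocation_ratio,
    alpha = design$alpha,
    omega = design$omega,
    control_events = design$control_events,
    effects = list(
      scale = "log_hr",
      target_I = design$target_effect_I,
      target_D = design$target_effect_D,
      null_I = design$null_effect_I,
      null_D = design$null_effect_D
    ),
    i_equals_d = design$i_equals_d,
    binding = design$binding
  ))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}
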