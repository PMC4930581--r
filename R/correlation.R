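#' Correlation structure of the stagewise treatment-effect z-statistics
#'
#' In a MAMS trial all stagewise log-hazard-ratio estimates are correlated:
#' across stages because later analyses accumulate the events of earlier ones
#' (nested information), and across arms because every comparison shares the
#' same control group.
#'
#' \code{between_stage_corr} returns the \eqn{J \times J} matrix \eqn{R} with
#' \eqn{R_{jj'} = \sqrt{e_j / e_{j'}}} for \eqn{j \le j'}, the correlation of
#' estimates based on nested event sets with control-arm event counts
#' \eqn{e_j}. The definitive-outcome events of the final stage are treated as
#' the continuation of the same accumulating-information process as the
#' intermediate-outcome events of the interim stages.
#'
#' \code{between_arm_corr} returns the \eqn{K \times K} matrix \eqn{C} with
#' unit diagonal and all off-diagonal entries \eqn{A/(A+1)}, the correlation
#' induced by the shared control arm under allocation ratio \eqn{A}.
#'
#' \code{joint_corr} assembles the \eqn{JK \times JK} correlation of the
#' stacked statistics \eqn{(Z_{11}, \dots, Z_{J1}, \dots, Z_{1K}, \dots,
#' Z_{JK})} (stage varying fastest): same-arm blocks equal \eqn{R},
#' same-stage cross-arm entries equal \eqn{C_{kk'}}, and cross-arm
#' cross-stage entries factorise as \eqn{C_{kk'} R_{jj'}}, which follows from
#' the shared-control accumulating-information normal model.
#'
#' @param design a \code{\link{mams_design}}.
#' @param K number of experimental arms.
#' @param A positive allocation ratio.
#' @return A correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @examples
#' between_arm_corr(5, 0.5)  # off-diagonals 1/3
#' d <- mams_design(4, 5, 0.5, alpha = c(0.5, 0.25, 0.1, 0.025),
#'                  omega = c(0.95, 0.95, 0.95, 0.9),
#'                  control_events = c(113, 216, 334, 403),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' between_stage_corr(d)[1, 4]  # sqrt(113/403)
#' @export
between_stage_corr <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  e <- design$control_events
  if (any(e <= 0)) stop("event counts must be positive", call. = FALSE)
  R <- outer(e, e, function(a, b) sqrt(pmin(a, b) / pmax(a, b)))
  diag(R) <- 1
  R
}

#' @rdname between_stage_corr
#' @export
between_arm_corr <- function(K, A) {
  if (length(K) != 1L || K < 1 || K != round(K))
    stop("`K` must be a single integer >= 1", call. = FALSE)
  if (length(A) != 1L || !is.finite(A) || A <= 0)
    stop("`A` must be a single positive number", call. = FALSE)
  C <- matrix(A / (A + 1), nrow = K, ncol = K)
  diag(C) <- 1
  C
}

#' @rdname between_stage_corr
#' @export
joint_corr <- function(design) {
  stopifnot(inherits(design, "mams_design"))
  R <- between_stage_corr(design)
  C <- between_arm_corr(design$n_arms, design$allocation_ratio)
  # off-diagonal blocks scale R by the between-arm correlation
  V <- kronecker(C, R)
  ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10)
    stop(sprintf(
      "joint correlation matrix is not positive semi-definite (smallest eigenvalue %.3e)",
      ev), call. = FALSE)
  V
}

# Lower-orthant multivariate-normal probability P(Z_1 < u_1, ..., Z_d < u_d)
# under correlation `corr`. Coordinates with upper limit +Inf are dropped;
# any -Inf limit gives probability 0. Perfectly correlated coordinate pairs
# are collapsed (keeping the smaller limit) so that singular matrices from
# tied event counts integrate exactly. The Miwa algorithm is deterministic.
mvn_lower <- function(upper, corr, steps = 512L) {
  stopifnot(length(upper) == nrow(corr))
  if (any(upper == -Inf)) return(0)
  keep <- which(is.finite(upper))
  if (length(keep) == 0L) return(1)
  upper <- upper[keep]
  corr <- corr[keep, keep, drop = FALSE]
  # collapse duplicated (correlation-1) coordinates
  d <- length(upper)
  if (d > 1L) {
    drop <- rep(FALSE, d)
    for (i in seq_len(d - 1L)) {
      if (drop[i]) next
      for (j in seq(i + 1L, d)) {
        if (!drop[j] && corr[i, j] >= 1 - 1e-12) {
          upper[i] <- min(upper[i], upper[j])
          drop[j] <- TRUE
        }
      }
    }
    if (any(drop)) {
      upper <- upper[!drop]
      corr <- corr[!drop, !drop, drop = FALSE]
    }
  }
  if (length(upper) == 1L) return(stats::pnorm(upper))
  res <- mvtnorm::pmvnorm(lower = -Inf, upper = upper, corr = corr,
                          algorithm = mvtnorm::Miwa(steps = steps))
  err <- attr(res, "error")
  if (!is.null(err) && is.finite(err) && err > 1e-6)
    stop(sprintf("multivariate-normal integration error %.2e exceeds tolerance 1e-6",
                 err), call. = FALSE)
  as.numeric(res)
}
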