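#' Analytic operating characteristics of a MAMS design
#'
#' Computes the design's stagewise table together with the overall pairwise
#' type I error rate and power (\code{\link{pairwise_error}},
#' \code{\link{pairwise_power}}), the maximum pairwise error rate
#' (\code{\link{max_pairwise_error}}) and the maximum familywise error rate
#' (\code{\link{max_fwer}}).
#'
#' @param object a \code{\link{mams_design}}.
#' @param ... unused.
#' @return An object of class \code{"summary.mams_design"}.
#' @examples
#' d <- mams_design(4, 5, 0.5, alpha = c(0.5, 0.25, 0.1, 0.025),
#'                  omega = c(0.95, 0.95, 0.95, 0.9),
#'                  control_events = c(113, 216, 334, 403),
#'                  target_effect_I = log(0.75), target_effect_D = log(0.75))
#' summary(d)
#' @export
summary.mams_design <- function(object, ...) {
  max_pwer <- tryCatch(max_pairwise_error(object)$value,
                       error = function(e) NA_real_)
  structure(list(
    design = object,
    stage_table = data.frame(
      stage = seq_len(object$n_stages),
      outcome = if (object$i_equals_d) rep("D", object$n_stages) else
        c(rep("I", object$n_stages - 1L), "D"),
      target_hr = exp(c(rep(object$target_effect_I, object$n_stages - 1L),
                        object$target_effect_D)),
      alpha = object$alpha,
      omega = object$omega,
      control_events = object$control_events
    ),
    pwer = pairwise_error(object)$value,
    power = pairwise_power(object)$value,
    max_pwer = max_pwer,
    max_fwer = max_fwer(object)$value
  ), class = "summary.mams_design")
}

#' @export
print.summary.mams_design <- function(x, ...) {
  d <- x$design
  cat(sprintf("MAMS design: %d experimental arm%s, %d stage%s, allocation ratio A = %g\n\n",
              d$n_arms, if (d$n_arms > 1) "s" else "",
              d$n_stages, if (d$n_stages > 1) "s" else "",
              d$allocation_ratio))
  tab <- x$stage_table
  tab$target_hr <- sprintf("%.3f", tab$target_hr)
  tab$alpha <- sprintf("%.4f", tab$alpha)
  tab$omega <- sprintf("%.4f", tab$omega)
  print(tab, row.names = FALSE)
  cat(sprintf("\nOverall pairwise type I error rate (joint null): %.4f\n", x$pwer))
  cat(sprintf("Overall pairwise power:                          %.4f\n", x$power))
  if (is.na(x$max_pwer)) {
    cat("Maximum pairwise error rate: global-null value above (I = D, binding)\n")
  } else {
    cat(sprintf("Maximum pairwise error rate (strong sense):      %.4f\n", x$max_pwer))
  }
  cat(sprintf("Maximum familywise error rate (strong sense):    %.4f\n", x$max_fwer))
  invisible(x)
}

#' Write a design report to disk
#'
#' Renders the \code{\link{summary.mams_design}} of a design as an
#' aligned-text file and/or a CSV of the stagewise table with the overall
#' rates appended as an \code{"Overall"} row.
#'
#' @param design a \code{\link{mams_design}}.
#' @param out_dir output directory (created if absent).
#' @param formats character subset of \code{c("txt", "csv")}.
#' @param basename stem for the output file names.
#' @return Invisibly, the paths written.
#' @export
design_report <- function(design, out_dir = ".", formats = c("txt", "csv"),
                          basename = "mams_design_report") {
  stopifnot(inherits(design, "mams_design"))
  formats <- match.arg(formats, c("txt", "csv"), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  s <- summary(design)
  paths <- character(0)
  if ("txt" %in% formats) {
    p <- file.path(out_dir, paste0(basename, ".txt"))
    txt <- utils::capture.output(print(s))
    writeLines(txt, p)
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    p <- file.path(out_dir, paste0(basename, ".csv"))
    tab <- s$stage_table
    tab$stage <- as.character(tab$stage)
    overall <- data.frame(stage = "Overall", outcome = "", target_hr = NA_real_,
                          alpha = s$pwer, omega = s$power,
                          control_events = NA_real_)
    out <- rbind(tab, overall)
    out$max_pwer <- c(rep(NA_real_, nrow(tab)), s$max_pwer)
    out$max_fwer <- c(rep(NA_real_, nrow(tab)), s$max_fwer)
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a design's correlation matrices as CSV
#'
#' Writes the between-stage, between-arm and joint correlation matrices of
#' the design's stagewise z-statistics (see
#' \code{\link{between_stage_corr}}) for external inspection.
#'
#' @param design a \code{\link{mams_design}}.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_correlations <- function(design, out_dir = ".") {
  stopifnot(inherits(design, "mams_design"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mats <- list(between_stage = between_stage_corr(design),
               between_arm = between_arm_corr(design$n_arms,
                                              design$allocation_ratio),
               joint = joint_corr(design))
  paths <- vapply(names(mats), function(nm) {
    p <- file.path(out_dir, paste0("corr_", nm, ".csv"))
    utils::write.csv(mats[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}
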