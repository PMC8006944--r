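#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a minimal-model fit
#'
#' @param x An `ocmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `cv_percent` (NA for fixed parameters), `fixed`.
#' @exportS3Method generics::tidy
tidy.ocmm_fit <- function(x, ...) {
  terms <- .param_names
  cv <- rep(NA_real_, length(terms))
  names(cv) <- terms
  cv[x$free] <- x$cv_percent[x$free]
  tibble::tibble(
    term = terms,
    estimate = unname(x$estimates[terms]),
    cv_percent = unname(cv),
    fixed = !(terms %in% x$free)
  )
}

#' One-row summary of a minimal-model fit
#'
#' @param x An `ocmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: approach, objective, convergence flag, number
#'   of observations, MCR and the four responsivity indices.
#' @exportS3Method generics::glance
glance.ocmm_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(approach = x$approach, objective = x$objective,
                   converged = x$converged, n_obs = nrow(x$prediction),
                   mcr = unname(x$estimates["k01"])),
    x$indices
  )
}

#' Observation-level results of a minimal-model fit
#'
#' @param x An `ocmm_fit`.
#' @param ... Unused.
#' @return The sample tibble with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.ocmm_fit <- function(x, ...) x$prediction

#' Plot a fit against its data
#'
#' Observed C-peptide samples with the fitted model trajectory evaluated on
#' a dense grid.
#'
#' @param object An `ocmm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ocmm_fit <- function(object, ...) {
  est <- as.list(object$estimates)
  kin <- kinetic_params(est$k01, est$k12, est$k21)
  sec <- secretion_params(est$k_d, est$alpha, est$beta, object$signal$G_b)
  t_dense <- seq(0, max(object$prediction$time_min), by = 1)
  curve <- tibble::tibble(
    time_min = t_dense,
    cpeptide_pmol_L = ocmm_predict_fast(kin, sec, object$signal, t_dense,
                                        cp_basal = object$cp_basal, h = 0.5)
  )
  ggplot2::ggplot(object$prediction,
                  ggplot2::aes(x = .data$time_min, y = .data$cpeptide_pmol_L)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "C-peptide (pmol/L)",
                  title = paste(object$approach, "fit"),
                  subtitle = sprintf("MCR = %.3f 1/min, phi_tot = %.1f x 1e-9/min",
                                     object$estimates[["k01"]],
                                     object$indices$phi_tot)) +
    ggplot2::theme_minimal()
}

#' Tidy an in-silico assessment
#'
#' @param x An `ocmm_assessment`.
#' @param ... Unused.
#' @return The tidy per-fit results tibble (`id`, `source_id`, `approach`,
#'   `parameter`, `estimate`, `truth`, `ard_percent`).
#' @exportS3Method generics::tidy
tidy.ocmm_assessment <- function(x, ...) x$results

#' Summary medians of an in-silico assessment
#'
#' @param x An `ocmm_assessment`.
#' @param ... Unused.
#' @return The per-approach median [25th, 75th] MARD summary tibble.
#' @exportS3Method generics::glance
glance.ocmm_assessment <- function(x, ...) x$summary

#' Plot recovery scores by approach
#'
#' Boxplots of per-subject MARD for the clearance rate and the total
#' responsivity index, by identification approach.
#'
#' @param object An `ocmm_assessment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ocmm_assessment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scores,
                              c("mard_mcr", "mard_phi_tot"),
                              names_to = "score", values_to = "value")
  long$score <- ifelse(long$score == "mard_mcr", "MCR", "phi_tot")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$approach, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~score) +
    ggplot2::labs(x = NULL, y = "MARD (%)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic cohort's sampled curves
#'
#' Glucose and C-peptide sample trajectories for every subject in a cohort.
#'
#' @param cohort A cohort tibble with a `data` list-column.
#' @return A ggplot.
#' @export
plot_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), "data" %in% names(cohort))
  long <- tidyr::unnest(cohort[, c("id", "data")], "data") |>
    tidyr::pivot_longer(c("glucose_mmol_L", "cpeptide_pmol_L"),
                        names_to = "analyte", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                     group = .data$id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
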