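#' Plot a work ensemble with its Jarzynski average
#'
#' Replicate work profiles in grey with the Jarzynski free-energy estimate
#' overlaid in black, the standard presentation of pulling ensembles.
#'
#' @param object A `work_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.work_ensemble <- function(object, ...) {
  pmf <- jarzynski_pmf(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$extension, .data$work,
                               group = .data$replicate)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_line(data = pmf, inherit.aes = FALSE,
                       ggplot2::aes(.data$extension, .data$delta_g),
                       colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = "extension (Å)", y = "work (kcal/mol)",
                  title = "Work profiles and Jarzynski average") +
    ggplot2::theme_minimal()
}

#' Plot a PMF profile on the strain axis
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$strain, .data$delta_g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "strain (%)", y = expression(Delta * G ~ "(kcal/mol)"),
                  title = "Potential of mean force") +
    ggplot2::theme_minimal()
}

#' Plot a force profile on the strain axis
#'
#' @param object A `force_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$strain, .data$force_pn)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "strain (%)", y = "force (pN)",
                  title = "Force profile") +
    ggplot2::theme_minimal()
}

#' Plot cohort percentages with standard-error bars
#'
#' @param object A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  has_cohort <- "cohort" %in% names(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$category, .data$pct))
  if (has_cohort) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$cohort),
                               position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$pct - .data$se, ymax = .data$pct + .data$se,
                     group = .data$cohort),
        position = ggplot2::position_dodge(0.9), width = 0.2)
  } else {
    p <- p + ggplot2::geom_col(fill = "grey40") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$pct - .data$se, ymax = .data$pct + .data$se),
        width = 0.2)
  }
  p + ggplot2::labs(x = NULL, y = "mutations (%)") +
    ggplot2::theme_minimal()
}
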