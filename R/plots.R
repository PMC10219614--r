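#' Plot spectra, optionally as group means
#'
#' @param data Long tibble with `wavenumber`, `intensity` and optionally
#'   `group` columns.
#' @param by_group Average within group and colour by group label.
#' @return A ggplot.
#' @export
plot_spectra <- function(data, by_group = "group" %in% names(data)) {
  if (by_group) {
    means <- data |>
      dplyr::group_by(.data$group, .data$wavenumber) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
    ggplot2::ggplot(means, ggplot2::aes(
      .data$wavenumber, .data$intensity, colour = .data$group
    )) +
      ggplot2::geom_line() +
      ggplot2::scale_colour_manual(values = c(cancer = "#c0392b", control = "#27ae60")) +
      spectra_axes()
  } else {
    ggplot2::ggplot(data, ggplot2::aes(.data$wavenumber, .data$intensity)) +
      ggplot2::geom_line() +
      spectra_axes()
  }
}

spectra_axes <- function() {
  list(
    ggplot2::labs(
      x = expression("Raman shift (cm"^-1 * ")"),
      y = "Intensity (a.u.)"
    ),
    ggplot2::theme_minimal()
  )
}

#' @describeIn run_univariate Difference spectrum with the
#'   FDR-significant wavenumbers highlighted.
#' @param object A `univariate_report`.
#' @export
autoplot.univariate_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(d, .data$significant),
      colour = "#c0392b", size = 0.7
    ) +
    ggplot2::labs(
      x = expression("Raman shift (cm"^-1 * ")"),
      y = "Mean difference, cancer - control (SNV units)",
      title = sprintf(
        "Pointwise differences; %d of %d wavenumbers significant at FDR %g",
        sum(d$significant), nrow(d), object$target_fdr
      )
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn loocv_pca_lda ROC curve of the LOOCV decision scores.
#' @param object A `sers_cv`.
#' @export
autoplot.sers_cv <- function(object, ...) {
  r <- object$results
  curve <- roc_curve(r$score, r$true_label)
  auc <- roc_auc(r$score, r$true_label)
  ggplot2::ggplot(curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("LOOCV ROC (AUC = %.3f)", auc)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pca Scree plot of cumulative explained variance.
#' @param object A `pca_fit`.
#' @param ... Unused.
#' @export
autoplot.pca_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$cumulative_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Component", y = "Cumulative variance explained (%)") +
    ggplot2::theme_minimal()
}
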