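#' Plot spectra as overlaid curves
#'
#' One line per spectrum, colored by sample; replicates share a color. Gaps
#' from region trimming are left unconnected.
#'
#' @param spectra A spectra table.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  spectra <- as_spectra(spectra)
  spectra <- spectra |>
    dplyr::group_by(.data$sample, .data$replicate) |>
    dplyr::mutate(segment = c(0, cumsum(diff(.data$wavelength_nm) >
                                          1.5 * min(diff(.data$wavelength_nm))))) |>
    dplyr::ungroup()
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                               color = .data$sample,
                               group = interaction(.data$sample,
                                                   .data$replicate,
                                                   .data$segment))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance (a.u.)",
                  color = "sample") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation error against the number of latent variables
#'
#' @param object A `spectrocal_cv` tibble from [loocv_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrocal_cv <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$n_pc, y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV (mg/g)") +
    ggplot2::theme_minimal()
}

#' Grouped-bar comparison of RMSECV across preprocessing methods
#'
#' One bar group per component, one bar per preprocessing method - the
#' standard visual summary of a multi-method calibration comparison.
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_report <- function(object, ...) {
  cells <- report_cells(object) |>
    dplyr::filter(!is.na(.data$rmsecv))
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = factor(.data$component_index),
                               y = .data$rmsecv, fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "component", y = "RMSECV (mg/g)", fill = "method") +
    ggplot2::theme_minimal()
}

#' Dot plot of robust outlier scores for one component
#'
#' @param object An `outlier_report` from [detect_outliers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outlier_report <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$sample, y = .data$score,
                               color = .data$flagged)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "sample", y = "robust z-score",
                  title = attr(object, "component_name")) +
    ggplot2::theme_minimal()
}
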