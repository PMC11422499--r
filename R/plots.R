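#' Plot one or more spectra
#'
#' @param s Spectrum tibble; facetted by `source` when several sources
#'   are stacked in one tibble.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(s) {
  validate_spectrum(dplyr::arrange(dplyr::distinct(
    s, .data$wavelength, .keep_all = TRUE), .data$wavelength))
  kind <- if ("kind" %in% names(s)) s$kind[1] else "absorption"
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$wavelength, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = paste0(kind, if (nzchar(spectral_units(kind)))
                    paste0(" (", spectral_units(kind), ")") else "")) +
    ggplot2::theme_minimal()
  if ("source" %in% names(s) && dplyr::n_distinct(s$source) > 1) {
    p <- p + ggplot2::facet_wrap(~source, scales = "free_y")
  }
  p
}

#' @export
autoplot.acs_products <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$wavelength, y = .data$value,
                                 colour = .data$product)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "coefficient (m^-1)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.filterpad_result <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$wavelength, y = .data$value,
                                 colour = .data$product)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorption (m^-1)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.detrital_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$observed[c("wavelength", "value")],
                       series = "measured")
  fit <- dplyr::mutate(object$fitted[c("wavelength", "value")],
                       series = "fitted")
  dplyr::bind_rows(obs, fit) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$wavelength, y = .data$value,
                                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "detrital absorption (m^-1)",
                  colour = NULL,
                  subtitle = sprintf("%s, S = %.4f", object$model, object$s)) +
    ggplot2::theme_minimal()
}

#' Plot a particle size distribution
#'
#' Volume, number and area distributions on the logarithmic size axis.
#'
#' @param psd Tibble from [process_lisst_run()] or [number_to_area()].
#' @return A ggplot object.
#' @export
plot_psd <- function(psd) {
  psd %>%
    dplyr::select(dplyr::all_of(c("d_um", "pvc_ul_per_l", "n_per_ml",
                                  "a_m2_per_ml"))) %>%
    tidyr::pivot_longer(-dplyr::all_of("d_um"), names_to = "distribution",
                        values_to = "value") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$d_um, y = .data$value)) +
    ggplot2::geom_col(width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~distribution, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "diameter (um)", y = NULL) +
    ggplot2::theme_minimal()
}
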