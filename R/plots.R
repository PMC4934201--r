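#' Plot a spectrum
#'
#' @param object A [sif_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot sif_spectrum
autoplot.sif_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = sif_unit(object))
}

#' Plot retrieval statistics along a sweep
#'
#' Mean retrieved fluorescence with +/- 1 sd error bars for each algorithm,
#' faceted by band, with the injected truth drawn as a dashed line; the usual
#' way Monte-Carlo retrieval evaluations are displayed.
#'
#' @param report A sweep report tibble (from [sweep_cab()], [sweep_lai()] or
#'   [sweep_sza()]).
#' @param x Name of the sweep column (`"cab"`, `"lai"` or `"sza_deg"`).
#' @return A ggplot.
#' @export
plot_retrieval_sweep <- function(report, x) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data[[x]], y = .data$mean,
                                       colour = .data$algorithm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), colour = "grey40",
                       linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = x, y = "retrieved SIF (mW m-2 sr-1 nm-1)")
}

#' Plot a diurnal retrieval series against PAR
#'
#' @param series A tibble from [diurnal_simulation()].
#' @return A ggplot with SIF on the left axis and scaled PAR overlaid.
#' @export
plot_diurnal <- function(series) {
  sc <- max(series$f_value) / max(series$par)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$hour)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$par * sc), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$f_value, colour = .data$target)) +
    ggplot2::facet_grid(band ~ algorithm) +
    ggplot2::labs(x = "local time (h)", y = "retrieved SIF (mW m-2 sr-1 nm-1)",
                  caption = "grey line: PAR (rescaled)")
}
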