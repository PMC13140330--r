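# ggplot2 visualisation helpers for maps and result tables.

#' Plot one slice of a volume as a raster map
#'
#' @param vol a [volume_image] (complex volumes are plotted as magnitude).
#' @param slice slice index along the third axis.
#' @param limits optional fill limits.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = 1, limits = NULL, title = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  sl <- vol$data[, , slice]
  if (is.complex(sl)) sl <- abs(sl)
  d <- dim(sl)
  df <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2]) * vol$voxel_size[1],
    y = rep(seq_len(d[2]), each = d[1]) * vol$voxel_size[2],
    value = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = title) +
    ggplot2::theme_minimal()
}

#' @method autoplot fatwater_result
#' @export
autoplot.fatwater_result <- function(object, slice = 1, ...) {
  plot_slice(object$pdff, slice = slice, limits = c(0, 1),
             title = "Proton-density fat fraction")
}

#' @method autoplot pvc_result
#' @export
autoplot.pvc_result <- function(object, ...) {
  d <- dplyr::filter(object$values, .data$region != ".background")
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$corrected,
                                  colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "observed region mean (a.u.)",
                  y = "partial-volume corrected (a.u.)",
                  title = "Region-based partial volume correction") +
    ggplot2::theme_minimal()
}

#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc_mM, .data$si)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "nominal concentration (mM)",
                  y = "corrected signal intensity (a.u.)",
                  title = sprintf("Reference calibration (R² = %.4f)",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Group comparison box plot for one parameter
#'
#' @param regions long region table from [process_study()].
#' @param parameter which parameter to plot (e.g. `"atsc"`).
#' @param fat_corrected use the fat-corrected values where available.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(regions, parameter = "atsc",
                                  fat_corrected = TRUE) {
  d <- dplyr::filter(regions, .data$parameter == !!parameter, !.data$excluded)
  if (fat_corrected && "value_fc" %in% names(d) && any(is.finite(d$value_fc))) {
    d$plot_value <- d$value_fc
  } else {
    d$plot_value <- d$value
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$plot_value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = parameter, title = parameter) +
    ggplot2::theme_minimal()
}
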