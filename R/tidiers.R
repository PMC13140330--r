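# broom-style tidiers for the fitted objects.

#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points,
                 valid = x$valid)
}

#' @method tidy pvc_result
#' @export
tidy.pvc_result <- function(x, ...) x$values

#' @method glance pvc_result
#' @export
glance.pvc_result <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$values),
                 condition_number = x$condition_number,
                 residual_norm = x$residual_norm, flagged = x$flagged)
}

#' @method tidy fatwater_result
#' @export
tidy.fatwater_result <- function(x, masks = NULL, ...) {
  if (is.null(masks)) {
    p <- x$pdff$data
    return(tibble::tibble(parameter = "pdff",
                          median = stats::median(p[is.finite(p)]),
                          support_voxels = sum(is.finite(p))))
  }
  dplyr::mutate(region_means(x$pdff, masks), parameter = "pdff")
}
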