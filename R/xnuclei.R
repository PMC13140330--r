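# X-nuclei quantification: region-based partial volume correction through a
# geometric transfer matrix (GTM), relaxation correction, reference-tube
# calibration, and concentration quantification.

#' Region-based partial volume correction
#'
#' Builds the geometric transfer matrix `M` with
#' `M[i, j] = mean over region i of the PSF-blurred indicator of region j`
#' (the background is included as an explicit region to absorb spill-in) and
#' solves `M s = b` by least squares, where `b` holds the observed region
#' means. With a delta PSF, `M` is the identity and the corrected values
#' equal the observed means.
#'
#' @param image a [volume_image] on the mask grid.
#' @param masks a [region_mask_set] on the same grid.
#' @param psf a [psf_spec()] describing the acquisition blur.
#' @param condition_limit warn and flag when the GTM condition number
#'   exceeds this.
#' @return A `pvc_result`: tibble `values` (`region`, `class`, `observed`,
#'   `corrected`, `voxel_count`), the matrix `gtm`, `condition_number`,
#'   `residual_norm` and `flagged`.
#' @export
region_pvc <- function(image, masks, psf, condition_limit = 1e4) {
  stopifnot(inherits(image, "volume_image"))
  if (!identical(dim(image$data), dim(masks$label_map$data))) {
    abort("image and masks must share a grid")
  }
  dims <- dim(image$data)
  vox <- image$voxel_size
  lab <- masks$label_map$data
  tab <- masks$label_table[masks$label_table$n_voxels > 0, ]
  # explicit background region (label 0)
  regions <- c(tab$name, ".background")
  supports <- c(lapply(tab$label, function(l) lab == l), list(lab == 0L))
  n <- length(regions)
  M <- matrix(0, n, n, dimnames = list(regions, regions))
  for (j in seq_len(n)) {
    ind <- array(as.numeric(supports[[j]]), dims)
    blurred <- apply_psf(ind, psf, vox)
    for (i in seq_len(n)) M[i, j] <- mean(blurred[supports[[i]]])
  }
  b <- vapply(supports, function(s) mean(image$data[s]), numeric(1))
  kappa <- kappa(M, exact = TRUE)
  fit <- stats::lsfit(M, b, intercept = FALSE)
  s <- unname(fit$coefficients)
  flagged <- is.finite(kappa) && kappa > condition_limit
  if (flagged) {
    warn(sprintf("GTM condition number %.3g exceeds limit %.3g; PVC may be unstable",
                 kappa, condition_limit))
  }
  structure(list(
    values = tibble::tibble(
      region = regions,
      class = c(tab$class, "background"),
      observed = b, corrected = s,
      voxel_count = vapply(supports, sum, numeric(1))),
    gtm = M, condition_number = kappa,
    residual_norm = sqrt(sum(fit$residuals^2)),
    flagged = flagged
  ), class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat(sprintf("<pvc_result> %d regions, GTM condition number %.3g%s\n",
              nrow(x$values), x$condition_number,
              if (x$flagged) " [flagged]" else ""))
  print(x$values)
  invisible(x)
}

#' Relaxation factor from sequence timing
#'
#' Saturation-recovery / transverse-decay signal factor
#' `(1 - exp(-TR/T1)) * exp(-TE/T2*)` for given timing and relaxation
#' constants (all in ms).
#'
#' @param tr_ms,te_ms repetition and echo time, ms.
#' @param t1_ms,t2star_ms relaxation constants, ms.
#' @return Factor in (0, 1].
#' @export
relaxation_factor_from_timing <- function(tr_ms, te_ms, t1_ms, t2star_ms) {
  stopifnot(tr_ms > 0, t1_ms > 0, t2star_ms > 0, te_ms >= 0)
  (1 - exp(-tr_ms / t1_ms)) * exp(-te_ms / t2star_ms)
}

#' Correct PVC signal intensities for relaxation weighting
#'
#' Divides each region's corrected signal by the relaxation factor of its
#' class, removing the differential saturation/decay weighting between
#' muscle, fat and the reference solutions.
#'
#' @param pvc a `pvc_result` (or its `values` tibble).
#' @param factors named per-class factors in (0, 1\], e.g.
#'   [default_relaxation_factors()]; the background row passes through
#'   unchanged.
#' @return The `values` tibble with an `si_corrected` column.
#' @export
relaxation_correct <- function(pvc, factors = default_relaxation_factors()) {
  vals <- if (inherits(pvc, "pvc_result")) pvc$values else tibble::as_tibble(pvc)
  cls <- vals$class
  f <- unname(factors[cls])
  f[cls == "background"] <- 1
  if (any(is.na(f))) {
    abort(sprintf("no relaxation factor for region(s): %s",
                  paste(vals$region[is.na(f)], collapse = ", ")))
  }
  if (any(f <= 0)) abort("relaxation factors must be positive")
  dplyr::mutate(vals, si_corrected = .data$corrected / f)
}

#' Calibrate signal intensity against the reference tubes
#'
#' Ordinary least squares of corrected tube signal intensity on nominal
#' concentration, `SI = slope * conc + intercept` (optionally forced
#' through zero).
#'
#' @param si corrected signal intensities of the reference tubes (a.u.).
#' @param conc_mM nominal tube concentrations (mM), at least two distinct.
#' @param intercept fit a free intercept (default) or force it to zero.
#' @return A `calibration_model`: `slope` (a.u./mM), `intercept` (a.u.),
#'   `r_squared`, `n_points`, `valid` (slope > 0).
#' @export
calibrate_references <- function(si, conc_mM, intercept = TRUE) {
  stopifnot(length(si) == length(conc_mM))
  if (length(si) < 2 || length(unique(conc_mM)) < 2) {
    abort("calibration needs >= 2 tubes with distinct concentrations")
  }
  fit <- if (intercept) lm(si ~ conc_mM) else lm(si ~ conc_mM + 0)
  cf <- coef(fit)
  slope <- unname(if (intercept) cf[2] else cf[1])
  icpt <- if (intercept) unname(cf[1]) else 0
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((si - mean(si))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = slope, intercept = icpt, r_squared = r2,
                 n_points = length(si), valid = is.finite(slope) && slope > 0,
                 data = tibble::tibble(conc_mM = conc_mM, si = si)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> SI = %.4g * conc + %.4g (R^2 = %.6f, n = %d)%s\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (!x$valid) " [invalid]" else ""))
  invisible(x)
}

#' Convert corrected signal intensities to concentrations
#'
#' `conc = (SI - intercept) / slope`; negative results are clipped to zero
#' and flagged.
#'
#' @param si corrected signal intensities (a.u.).
#' @param model a `calibration_model` with positive slope.
#' @return Tibble with `si`, `conc_mM`, `clipped`.
#' @export
quantify_concentration <- function(si, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.finite(model$slope) || model$slope <= 0) {
    abort("calibration slope must be positive for quantification")
  }
  conc <- (si - model$intercept) / model$slope
  clipped <- conc < 0
  conc[clipped] <- 0
  tibble::tibble(si = si, conc_mM = conc, clipped = clipped)
}

#' Per-region apparent tissue ion concentration from one X-nuclei volume
#'
#' Runs the full quantification chain: region PVC, relaxation correction,
#' calibration on the reference tubes, and conversion to concentration.
#'
#' @param image X-nuclei [volume_image] (`na`, `na_ir` or `k`).
#' @param masks a [region_mask_set] on the image grid carrying nominal tube
#'   concentrations.
#' @param psf a [psf_spec()].
#' @param factors per-class relaxation factors.
#' @param nucleus which nominal concentration column to calibrate on;
#'   defaults to the image's modality tag. For `na_ir` no calibration is
#'   performed and corrected signal intensities are returned as `value`.
#' @param intercept free calibration intercept (default) or through zero.
#' @return Tibble of non-background regions: `region`, `class`, `parameter`,
#'   `value` (mM, or a.u. for `na_ir`), `si_raw`, `si_corrected`,
#'   `voxel_count`, `excluded`, `exclusion_reason`; the calibration model
#'   (if any) and the `pvc_result` are attached as attributes.
#' @export
quantify_xnuclei <- function(image, masks, psf,
                             factors = default_relaxation_factors(),
                             nucleus = NULL, intercept = TRUE) {
  nucleus <- nucleus %||% image$modality_tag
  pvc <- region_pvc(image, masks, psf)
  corr <- relaxation_correct(pvc, factors)
  parameter <- switch(nucleus, na = "atsc", k = "atpc", na_ir = "ir",
                      abort(sprintf("unknown nucleus '%s'", nucleus)))
  model <- NULL
  out <- dplyr::filter(corr, .data$class != "background")
  if (nucleus %in% c("na", "k")) {
    col <- if (nucleus == "na") "na_mM" else "k_mM"
    tubes <- dplyr::filter(out, .data$class == "reference_tube")
    nominal <- masks$label_table[[col]][match(tubes$region, masks$label_table$name)]
    model <- calibrate_references(tubes$si_corrected, nominal, intercept = intercept)
    qc <- quantify_concentration(out$si_corrected, model)
    out$value <- qc$conc_mM
    out$clipped <- qc$clipped
  } else {
    out$value <- out$si_corrected
    out$clipped <- FALSE
  }
  out <- tibble::tibble(
    region = out$region, class = out$class, parameter = parameter,
    value = out$value, si_raw = out$observed, si_corrected = out$si_corrected,
    voxel_count = out$voxel_count,
    excluded = FALSE, exclusion_reason = "",
    clipped = out$clipped)
  attr(out, "calibration") <- model
  attr(out, "pvc") <- pvc
  out
}
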