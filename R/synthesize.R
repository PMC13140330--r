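#' Noise specification
#'
#' @param model `"none"`, `"gaussian_complex"` (complex gradient-echo data)
#'   or `"rician_magnitude"` (magnitude data).
#' @param snr signal-to-noise ratio: mean signal of `reference_region` at the
#'   first echo divided by the per-channel noise SD.
#' @param reference_region region name defining the SNR.
#' @param seed integer seed fixing the full noise stream; `NULL` leaves the
#'   RNG state alone.
#' @export
noise_spec <- function(model = c("none", "gaussian_complex", "rician_magnitude"),
                       snr = 50, reference_region = "SOL", seed = NULL) {
  model <- match.arg(model)
  if (model != "none" && (!is.finite(snr) || snr <= 0)) {
    abort("SNR must be > 0 when noise is requested")
  }
  list(model = model, snr = snr, reference_region = reference_region, seed = seed)
}

#' Point-spread-function specification
#'
#' @param kernel `"delta"` (no blur) or `"gaussian"`.
#' @param fwhm_mm full width at half maximum in mm, recycled to 3 axes.
#' @export
psf_spec <- function(kernel = c("gaussian", "delta"), fwhm_mm = 15) {
  kernel <- match.arg(kernel)
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (kernel == "gaussian" && any(fwhm_mm <= 0)) abort("FWHM must be > 0")
  list(kernel = kernel, fwhm_mm = fwhm_mm)
}

# evaluate code with a temporary RNG state; restores the caller's stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable zero-padded Gaussian convolution of a 3D array
gaussian_blur3d <- function(arr, fwhm_mm, voxel_size) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  out <- arr
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / voxel_size[ax]
    if (sigma_vox < 1e-6) next
    # voxel-integrated Gaussian bins; 5 sigma support keeps the truncated
    # tail below 3e-7
    half <- max(1L, ceiling(5 * sigma_vox))
    x <- (-half):half
    k <- pnorm((x + 0.5) / sigma_vox) - pnorm((x - 0.5) / sigma_vox)
    k <- k / sum(k)
    out <- blur_axis(out, k, ax)
  }
  out
}

# convolve along one axis with zero padding, via a banded matrix product
blur_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - 1L - half
    idx <- seq_len(n)
    src <- idx + off
    keep <- src >= 1L & src <= n
    K[cbind(idx[keep], src[keep])] <- K[cbind(idx[keep], src[keep])] + kernel[j]
  }
  m <- matrix(a, nrow = n)
  b <- K %*% m
  aperm(array(b, d[perm]), order(perm))
}

apply_psf <- function(arr, psf, voxel_size) {
  if (psf$kernel == "delta") return(arr)
  gaussian_blur3d(arr, psf$fwhm_mm, voxel_size)
}

noise_sd_from_snr <- function(ideal, masks, noise) {
  ref <- region_indicator(masks, noise$reference_region)
  mean(abs(ideal[ref])) / noise$snr
}

#' Synthesize a complex multi-echo Dixon acquisition
#'
#' Voxel signal model:
#' `S(TE) = A (W + F sum_p a_p exp(i 2 pi f_p TE)) exp(i 2 pi psi TE) exp(-R2* TE)`
#' with `W = 1 - FF`, `F = FF` per region, field offset `psi` and a single
#' `R2*` decay. Complex Gaussian noise is added per channel when requested.
#'
#' @param truth a [phantom_truth()].
#' @param masks the proton-grid [region_mask_set] from [build_leg_phantom()].
#' @param echo_times echo times in ms, at least 3, strictly increasing.
#' @param spectrum a [fat_spectrum()]; must match the separation default for
#'   model-matched recovery.
#' @param noise a [noise_spec()] (`gaussian_complex` or `none`).
#' @return A complex [echo_series].
#' @export
synthesize_dixon <- function(truth, masks, echo_times = default_dixon_tes(),
                             spectrum = default_fat_spectrum(),
                             noise = noise_spec("none")) {
  if (length(echo_times) < 3) abort("Dixon synthesis needs at least 3 echoes")
  if (any(diff(echo_times) <= 0)) abort("echo times must be strictly increasing (non-zero spacing)")
  te_s <- echo_times / 1000
  amp <- region_param_map(masks, truth$regions, "amp")
  ff <- region_param_map(masks, truth$regions, "fat_fraction")
  psi <- region_param_map(masks, truth$regions, "field_offset_hz")
  r2s <- region_param_map(masks, truth$regions, "r2star")
  ph <- fat_phasor(spectrum, te_s)
  dims <- dim(masks$label_map$data)
  sig <- vapply(seq_along(te_s), function(e) {
    amp * ((1 - ff) + ff * ph[e]) * exp((2i * pi * psi - r2s) * te_s[e])
  }, complex(length(amp)))
  if (noise$model == "gaussian_complex") {
    sd0 <- noise_sd_from_snr(matrix(sig[, 1], nrow = length(amp)), masks, noise)
    sig <- with_local_seed(noise$seed, {
      n <- length(sig)
      sig + complex(real = rnorm(n, 0, sd0), imaginary = rnorm(n, 0, sd0))
    })
  } else if (noise$model != "none") {
    abort("Dixon echoes take 'gaussian_complex' or 'none' noise")
  }
  vols <- lapply(seq_along(te_s), function(e) {
    volume_image(array(sig[, e], dims), voxel_size = masks$label_map$voxel_size,
                 affine = masks$label_map$affine, modality_tag = "dixon_echo")
  })
  echo_series(vols, echo_times)
}

#' Default Dixon echo times (ms)
#' @export
default_dixon_tes <- function() seq(1.1, by = 1.2, length.out = 6)

#' Default MESE echo times (ms)
#' @export
default_mese_tes <- function() seq(10, by = 10, length.out = 16)

#' Synthesize a magnitude multi-echo spin-echo acquisition
#'
#' Tri-exponential forward model per voxel:
#' `S(TE) = A ((1-FF) exp(-TE/T2w) + FF (c1 exp(-TE/T2f1) + c2 exp(-TE/T2f2)))`
#' with the fat pair taken from the phantom truth. Rician noise is applied on
#' the magnitude when requested.
#'
#' @inheritParams synthesize_dixon
#' @param noise a [noise_spec()] (`rician_magnitude` or `none`).
#' @return A magnitude [echo_series].
#' @export
synthesize_mese <- function(truth, masks, echo_times = default_mese_tes(),
                            noise = noise_spec("none")) {
  if (length(echo_times) < 8) abort("MESE synthesis needs at least 8 echoes")
  if (any(diff(echo_times) <= 0)) abort("echo times must be strictly increasing")
  amp <- region_param_map(masks, truth$regions, "amp")
  ff <- region_param_map(masks, truth$regions, "fat_fraction")
  t2w <- region_param_map(masks, truth$regions, "water_t2", default = 1)
  fp <- truth$fat_t2
  dims <- dim(masks$label_map$data)
  sig <- vapply(echo_times, function(te) {
    amp * ((1 - ff) * exp(-te / t2w) +
             ff * (fp["c1"] * exp(-te / fp["t2f1"]) + fp["c2"] * exp(-te / fp["t2f2"])))
  }, numeric(length(amp)))
  if (noise$model == "rician_magnitude") {
    sd0 <- noise_sd_from_snr(matrix(sig[, 1], nrow = length(amp)), masks, noise)
    sig <- with_local_seed(noise$seed, {
      n <- length(sig)
      sqrt((sig + rnorm(n, 0, sd0))^2 + rnorm(n, 0, sd0)^2)
    })
  } else if (noise$model != "none") {
    abort("MESE magnitudes take 'rician_magnitude' or 'none' noise")
  }
  vols <- lapply(seq_along(echo_times), function(e) {
    volume_image(array(sig[, e], dims), voxel_size = masks$label_map$voxel_size,
                 affine = masks$label_map$affine, modality_tag = "mese_echo")
  })
  echo_series(vols, echo_times)
}

#' Synthesize a low-resolution X-nuclei acquisition
#'
#' The ideal image places, on each region's support, the region's apparent
#' value times the calibration slope times the relaxation factor of its
#' class (times the inversion-recovery weighting for `na_ir`); it is then
#' convolved with the PSF, offset, and Rician noise is added. Apparent
#' region values mix the tissue value with the fat compartment:
#' `(1-FF) v_tissue + FF v_fat`, with the fat constants shared with the
#' correction stage (aTSC_fat = 7.9 mM, aTPC_fat = 0 mM, IR_fat = 2.5 a.u.).
#'
#' @inheritParams synthesize_dixon
#' @param masks the X-nuclei-grid [region_mask_set].
#' @param nucleus `"na"`, `"na_ir"` or `"k"`.
#' @param psf a [psf_spec()].
#' @param calib named vector `c(slope, offset)`: a.u. per mM (per a.u. for
#'   `na_ir`) and a global baseline offset in a.u.
#' @param relaxation_factors named per-class factors in (0, 1\];
#'   see [default_relaxation_factors()].
#' @param noise a [noise_spec()] (`rician_magnitude` or `none`).
#' @return A [volume_image] tagged with the nucleus.
#' @export
synthesize_xnuclei <- function(truth, masks, nucleus = c("na", "na_ir", "k"),
                               psf = psf_spec("gaussian", 15),
                               calib = c(slope = 1, offset = 0),
                               relaxation_factors = default_relaxation_factors(),
                               noise = noise_spec("none")) {
  nucleus <- match.arg(nucleus)
  app <- apparent_region_values(truth, nucleus)
  reg <- truth$regions
  reg$apparent <- app
  vals <- region_param_map(masks, reg, "apparent")
  cls <- masks$label_table$class[match(as.vector(masks$label_map$data),
                                       masks$label_table$label)]
  fac <- unname(relaxation_factors[cls])
  if (any(is.na(fac) & !is.na(cls))) {
    abort(sprintf("no relaxation factor for class: %s",
                  paste(unique(cls[is.na(fac) & !is.na(cls)]), collapse = ", ")))
  }
  fac[is.na(fac)] <- 1
  dims <- dim(masks$label_map$data)
  ideal <- array(vals * fac * calib[["slope"]], dims)
  img <- apply_psf(ideal, psf, masks$label_map$voxel_size) + calib[["offset"]]
  if (noise$model == "rician_magnitude") {
    sd0 <- noise_sd_from_snr(img, masks, noise)
    img <- with_local_seed(noise$seed, {
      n <- length(img)
      array(sqrt((img + rnorm(n, 0, sd0))^2 + rnorm(n, 0, sd0)^2), dims)
    })
  } else if (noise$model != "none") {
    abort("X-nuclei magnitudes take 'rician_magnitude' or 'none' noise")
  }
  volume_image(img, voxel_size = masks$label_map$voxel_size,
               affine = masks$label_map$affine, modality_tag = nucleus)
}

# per-region apparent (fat-mixed) value for one nucleus
apparent_region_values <- function(truth, nucleus) {
  reg <- truth$regions
  fc <- truth$fat_constants
  tissue <- switch(nucleus,
    na = reg$na_mM,
    k = reg$k_mM,
    na_ir = reg$ir_factor * (truth$ir_gain * reg$na_mM + truth$ir_offset))
  vfat <- switch(nucleus, na = fc$atsc_fat, k = fc$atpc_fat, na_ir = fc$ir_fat)
  # reference tubes are pure solution: no fat compartment
  ff <- ifelse(reg$class == "reference_tube", 0, reg$fat_fraction)
  (1 - ff) * tissue + ff * vfat
}

#' Default per-class relaxation weighting factors
#'
#' Multiplicative signal factors accounting for saturation and transverse
#' decay differences between tissue and reference solutions. Either given
#' directly (as here) or computed from timing constants with
#' [relaxation_factor_from_timing()].
#' @export
default_relaxation_factors <- function() {
  c(muscle = 0.80, subcutaneous_fat = 0.75, bone = 0.75,
    reference_tube = 0.95, background = 1)
}
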