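# Cohort simulation: subject-level phantom truths drawn around the group
# presets, acquisition synthesis per subject, and an in-memory study object
# the pipeline can process directly.

#' Draw a subject-level phantom truth around a group preset
#'
#' Jitters the per-muscle fat fractions, water T2 and tissue ion
#' concentrations of the `"control"` or `"mfm"` preset so that subjects in
#' a simulated cohort differ realistically while the group means stay at
#' the preset values.
#'
#' @param preset `"control"` or `"mfm"`.
#' @param seed subject seed (fixes the jitter).
#' @param ... passed to [phantom_truth()] (grid sizes etc.).
#' @return A [phantom_truth()].
#' @export
subject_truth <- function(preset = c("control", "mfm"), seed = 1, ...) {
  preset <- match.arg(preset)
  reg <- phantom_regions(preset)
  reg <- with_local_seed(seed, {
    mus <- reg$class == "muscle"
    nm <- sum(mus)
    if (preset == "control") {
      reg$fat_fraction[mus] <- stats::runif(nm, 0.03, 0.08)
      reg$na_mM[mus] <- pmax(reg$na_mM[mus] + rnorm(nm, 0, 2), 1)
      reg$k_mM[mus] <- pmax(reg$k_mM[mus] + rnorm(nm, 0, 5), 1)
      reg$water_t2[mus] <- reg$water_t2[mus] + rnorm(nm, 0, 0.8)
    } else {
      reg$fat_fraction[mus] <- pmin(pmax(
        reg$fat_fraction[mus] + rnorm(nm, 0, 0.05), 0.10), 0.90)
      reg$na_mM[mus] <- pmax(reg$na_mM[mus] + rnorm(nm, 0, 5), 1)
      reg$k_mM[mus] <- pmax(reg$k_mM[mus] + rnorm(nm, 0, 5), 1)
      reg$water_t2[mus] <- reg$water_t2[mus] + rnorm(nm, 0, 1.5)
    }
    reg$field_offset_hz[mus] <- reg$field_offset_hz[mus] + rnorm(nm, 0, 5)
    reg
  })
  phantom_truth(regions = reg, ...)
}

#' Synthesize all four acquisitions for one subject
#'
#' @param truth a [phantom_truth()].
#' @param seed master seed; per-acquisition seeds are split from it.
#' @param snr named SNR list (`dixon`, `mese`, `xnuclei`); `NULL` entries or
#'   `noiseless = TRUE` disable noise.
#' @param psf X-nuclei [psf_spec()].
#' @param calib named list of per-nucleus calibration `c(slope, offset)`.
#' @param relaxation_factors per-class factors used by the generator (the
#'   quantification stage corrects with its own configured factors).
#' @param noiseless generate without any noise.
#' @return List with `truth`, `masks` (`h1`, `xn`), `dixon`, `mese`, `na`,
#'   `na_ir`, `k`.
#' @export
simulate_subject <- function(truth, seed = 1,
                             snr = list(dixon = 50, mese = 60, xnuclei = 40),
                             psf = psf_spec("gaussian", 15),
                             calib = default_xnuclei_calibration(),
                             relaxation_factors = default_relaxation_factors(),
                             noiseless = FALSE) {
  masks <- build_leg_phantom(truth)
  sub_seed <- function(k) (abs(seed) * 131L + k) %% 2147483629L
  nz <- function(model, which, k) {
    if (noiseless || is.null(snr[[which]])) noise_spec("none")
    else noise_spec(model, snr = snr[[which]], seed = sub_seed(k))
  }
  list(
    truth = truth, masks = masks,
    dixon = synthesize_dixon(truth, masks$h1, noise = nz("gaussian_complex", "dixon", 1L)),
    mese = synthesize_mese(truth, masks$h1, noise = nz("rician_magnitude", "mese", 2L)),
    na = synthesize_xnuclei(truth, masks$xn, "na", psf = psf, calib = calib$na,
                            relaxation_factors = relaxation_factors,
                            noise = nz("rician_magnitude", "xnuclei", 3L)),
    na_ir = synthesize_xnuclei(truth, masks$xn, "na_ir", psf = psf, calib = calib$na_ir,
                               relaxation_factors = relaxation_factors,
                               noise = nz("rician_magnitude", "xnuclei", 4L)),
    k = synthesize_xnuclei(truth, masks$xn, "k", psf = psf, calib = calib$k,
                           relaxation_factors = relaxation_factors,
                           noise = nz("rician_magnitude", "xnuclei", 5L))
  )
}

#' Default X-nuclei calibration factors of the generator
#'
#' Arbitrary scanner units per mM (per a.u. for the IR acquisition); the
#' quantification stage re-estimates the sodium/potassium scale from the
#' reference tubes, so these only set the synthetic signal scale.
#' @export
default_xnuclei_calibration <- function() {
  list(na = c(slope = 1.0, offset = 0),
       na_ir = c(slope = 1.0, offset = 0),
       k = c(slope = 0.6, offset = 0))
}

#' Simulate an in-memory two-group study
#'
#' @param n_control,n_mfm group sizes.
#' @param seed master seed; subject seeds are split deterministically.
#' @param ... passed to [simulate_subject()] (grids come from
#'   `truth_args`).
#' @param truth_args named list passed to [subject_truth()] /
#'   [phantom_truth()] to shrink the grids.
#' @return A `study` list: `subjects` (each with `id`, `group` and the
#'   [simulate_subject()] fields) and `control_group = "control"`.
#' @export
simulate_cohort_study <- function(n_control = 10, n_mfm = 9, seed = 1,
                                  truth_args = list(), ...) {
  mk <- function(i, preset) {
    sseed <- (abs(seed) * 104729L + i * 7919L +
                ifelse(preset == "mfm", 499979L, 0L)) %% 2147483629L
    truth <- do.call(subject_truth, c(list(preset = preset, seed = sseed), truth_args))
    c(list(id = sprintf("%s%02d", toupper(substr(preset, 1, 1)), i),
           group = preset),
      simulate_subject(truth, seed = sseed + 17L, ...))
  }
  subjects <- c(lapply(seq_len(n_control), mk, preset = "control"),
                lapply(seq_len(n_mfm), mk, preset = "mfm"))
  structure(list(subjects = subjects, control_group = "control"),
            class = "xmuscle_study")
}

#' @export
print.xmuscle_study <- function(x, ...) {
  grp <- table(vapply(x$subjects, `[[`, character(1), "group"))
  cat("<xmuscle_study>", paste(sprintf("%s n=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}
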