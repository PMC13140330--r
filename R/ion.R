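# Fat correction of tissue ion values, relative inversion-recovery sodium
# normalisation, and the two-compartment extracellular-volume model.

#' Fat-signal constants for tissue ion correction
#'
#' Concentration/intensity of the fat compartment used to remove the fat
#' contribution from apparent tissue values: aTSC_fat = 7.9 mM,
#' aTPC_fat = 0 mM, and the inversion-recovery sodium intensity of fully
#' fat-replaced muscle, IR_fat = 2.5 a.u. Values above the PDFF exclusion
#' threshold are excluded rather than corrected.
#'
#' @param atsc_fat,atpc_fat,ir_fat fat-compartment constants (mM, mM, a.u.).
#' @param pdff_exclusion_percent exclusion threshold in percent PDFF.
#' @export
fat_correction_constants <- function(atsc_fat = 7.9, atpc_fat = 0,
                                     ir_fat = 2.5, pdff_exclusion_percent = 50) {
  stopifnot(atsc_fat >= 0, atpc_fat >= 0, ir_fat >= 0,
            pdff_exclusion_percent > 0, pdff_exclusion_percent < 100)
  list(atsc_fat = atsc_fat, atpc_fat = atpc_fat, ir_fat = ir_fat,
       pdff_exclusion_percent = pdff_exclusion_percent)
}

# scalar/vector kernel: invert two-compartment areal mixing
# v = (1 - pdff) v_tissue + pdff v_fat  =>  v_tissue = (v - pdff v_fat)/(1 - pdff)
fat_correct_value <- function(value, pdff, fat_constant) {
  if (any(pdff >= 1, na.rm = TRUE)) abort("pdff must be < 1 (fraction)")
  if (any(pdff < 0, na.rm = TRUE)) abort("pdff must be >= 0")
  (value - pdff * fat_constant) / (1 - pdff)
}

#' Fat-correct apparent tissue values
#'
#' Removes the fat-compartment contribution from an apparent (fat-mixed)
#' region value by inverting the two-compartment areal mixing:
#' `v_fc = (v - pdff * v_fat) / (1 - pdff)`. Rows at or above the PDFF
#' exclusion threshold are flagged excluded and not corrected. This is the
#' exact inverse of the generator's fat mixing.
#'
#' @param data tibble with the value and PDFF columns.
#' @param value column holding the apparent value (mM or a.u.).
#' @param pdff column holding the region PDFF as a fraction in \[0, 1).
#' @param fat_constant fat-compartment value in the same unit as `value`
#'   (e.g. `fat_correction_constants()$atsc_fat`).
#' @param threshold_percent PDFF exclusion threshold in percent.
#' @return `data` with `value_fc` added and `excluded`/`exclusion_reason`
#'   updated.
#' @export
fat_correct <- function(data, value, pdff, fat_constant,
                        threshold_percent = 50) {
  v <- dplyr::pull(data, {{ value }})
  p <- dplyr::pull(data, {{ pdff }})
  if (any(p >= 1, na.rm = TRUE)) abort("pdff must be < 1 (fraction)")
  hit <- !is.na(p) & p >= threshold_percent / 100
  vfc <- rep(NA_real_, length(v))
  ok <- !hit & !is.na(p) & !is.na(v)
  vfc[ok] <- fat_correct_value(v[ok], p[ok], fat_constant)
  out <- dplyr::mutate(data, value_fc = vfc)
  if (!"excluded" %in% names(out)) out$excluded <- FALSE
  if (!"exclusion_reason" %in% names(out)) out$exclusion_reason <- ""
  out$excluded <- out$excluded | hit
  out$exclusion_reason <- ifelse(hit & out$exclusion_reason == "",
                                 "pdff_gt_threshold", out$exclusion_reason)
  out
}

#' Relative inversion-recovery sodium intensity
#'
#' Fits an ordinary-least-squares regression of fat-corrected IR intensity
#' on fat-corrected aTSC over the control muscle regions, then expresses
#' every region's IR intensity relative to the regression prediction. By
#' construction control values scatter around 1; values above 1 indicate a
#' higher intracellular sodium fraction, values below 1 an increased
#' extracellular volume.
#'
#' @param data tibble with one row per (subject, region), containing the
#'   fat-corrected IR and aTSC columns and a subject column.
#' @param ir_fc,atsc_fc columns with the fat-corrected IR intensity (a.u.)
#'   and aTSC (mM).
#' @param subject column identifying subjects.
#' @param control_ids subject identifiers forming the control population
#'   (>= 5 usable control regions required).
#' @return `data` with `relative_ir` added (rows with non-positive predicted
#'   denominator are `NA` and flagged); the `control_regression`
#'   (slope, intercept, n) is attached as an attribute and returned by
#'   `attr(, "control_regression")`.
#' @export
relative_ir <- function(data, ir_fc, atsc_fc, subject, control_ids) {
  ir <- dplyr::pull(data, {{ ir_fc }})
  na <- dplyr::pull(data, {{ atsc_fc }})
  subj <- dplyr::pull(data, {{ subject }})
  ctl <- subj %in% control_ids & is.finite(ir) & is.finite(na)
  if (sum(ctl) < 5) abort("relative IR needs >= 5 control regions with both values")
  fit <- lm(ir[ctl] ~ na[ctl])
  alpha <- unname(coef(fit)[2]); beta <- unname(coef(fit)[1])
  pred <- alpha * na + beta
  rel <- ifelse(is.finite(pred) & pred > 0, ir / pred, NA_real_)
  out <- dplyr::mutate(data, relative_ir = rel)
  if (!"excluded" %in% names(out)) out$excluded <- FALSE
  if (!"exclusion_reason" %in% names(out)) out$exclusion_reason <- ""
  bad <- is.finite(ir) & (!is.finite(pred) | pred <= 0)
  out$excluded <- out$excluded | bad
  out$exclusion_reason <- ifelse(bad & out$exclusion_reason == "",
                                 "nonpositive_ir_prediction", out$exclusion_reason)
  attr(out, "control_regression") <- list(slope = alpha, intercept = beta,
                                          n = sum(ctl),
                                          population = "control muscle regions")
  out
}

#' Two-compartment tissue model
#'
#' Tissue concentration as a volume-weighted mix of extracellular and
#' intracellular compartments: `conc = ve * C_e + (1 - ve) * C_i`.
#'
#' @param c_i,c_e intra- and extracellular concentrations (mM), distinct.
#' @export
two_compartment_model <- function(c_i, c_e) {
  stopifnot(c_i >= 0, c_e >= 0)
  if (isTRUE(all.equal(c_i, c_e))) abort("C_e must differ from C_i for inversion")
  list(c_i = c_i, c_e = c_e)
}

#' Intracellular concentration implied by a control tissue value
#'
#' Inverts the two-compartment mix at the healthy extracellular volume
#' fraction: `C_i = (conc - ve0 * C_e) / (1 - ve0)`.
#'
#' @param control_conc control-group tissue concentration (mM).
#' @param ve0 healthy extracellular volume fraction, in (0, 1); 0.07 for
#'   skeletal muscle.
#' @param c_e extracellular (serum) concentration (mM).
#' @return `C_i` in mM.
#' @export
infer_intracellular <- function(control_conc, ve0 = 0.07, c_e) {
  stopifnot(ve0 > 0, ve0 < 1)
  ci <- (control_conc - ve0 * c_e) / (1 - ve0)
  if (any(ci < 0)) abort("inconsistent inputs: implied intracellular concentration < 0")
  ci
}

#' Extracellular volume fraction explaining a tissue concentration
#'
#' `ve = (conc - C_i) / (C_e - C_i)`. Results outside \[0, 1\] are reported
#' clipped with a flag.
#'
#' @param conc tissue concentration (mM).
#' @param model a [two_compartment_model()].
#' @return Tibble with `ve` (clipped to \[0, 1\]), `ve_raw`, `out_of_range`.
#' @export
ecv_from_concentration <- function(conc, model) {
  ve_raw <- (conc - model$c_i) / (model$c_e - model$c_i)
  tibble::tibble(ve = pmin(pmax(ve_raw, 0), 1), ve_raw = ve_raw,
                 out_of_range = ve_raw < 0 | ve_raw > 1)
}
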