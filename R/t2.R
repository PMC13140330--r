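# Water T2 relaxometry from multi-echo spin-echo data: a tri-exponential
# model with a subject-calibrated fat T2 pair, fitted at region level.

#' Calibrate the fat T2 pair from subcutaneous fat
#'
#' Fits a bi-exponential decay to the mean signal of the subcutaneous-fat
#' region and returns the normalised fat pair used by the tri-exponential
#' water-T2 model. On non-convergence the configured defaults are returned
#' with a warning.
#'
#' @param mese magnitude [echo_series].
#' @param masks a [region_mask_set] on the MESE grid.
#' @param fat_region name of the subcutaneous-fat region.
#' @param defaults fallback fat pair `c(c1, t2f1, c2, t2f2)` (ms).
#' @return Named vector `c(c1, t2f1, c2, t2f2)` with `c1 + c2 = 1` and
#'   `t2f1 < t2f2`.
#' @export
calibrate_fat_t2 <- function(mese, masks,
                             fat_region = "SCF",
                             defaults = c(c1 = 0.55, t2f1 = 45, c2 = 0.45, t2f2 = 170)) {
  sel <- region_indicator(masks, fat_region)
  if (sum(sel) < 50) abort("fat calibration needs >= 50 subcutaneous fat voxels")
  y <- vapply(mese$volumes, function(v) mean(v$data[sel]), numeric(1))
  te <- mese$echo_times
  fit <- fit_biexp(te, y)
  if (is.null(fit)) {
    warn("fat T2 calibration did not converge; using configured defaults")
    return(defaults)
  }
  fit
}

# bi-exponential amplitude-normalised fit; NULL on failure
fit_biexp <- function(te, y) {
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a1 = 0.6 * y[1], t21 = 50, a2 = 0.4 * y[1], t22 = 180),
      lower = c(0, 5, 0, 60), upper = c(Inf, 150, Inf, 600),
      fn = function(p) y - (p[1] * exp(-te / p[2]) + p[3] * exp(-te / p[4])),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  p <- fit$par
  tot <- p["a1"] + p["a2"]
  if (!is.finite(tot) || tot <= 0) return(NULL)
  out <- if (p["t21"] <= p["t22"]) {
    c(c1 = unname(p["a1"] / tot), t2f1 = unname(p["t21"]),
      c2 = unname(p["a2"] / tot), t2f2 = unname(p["t22"]))
  } else {
    c(c1 = unname(p["a2"] / tot), t2f1 = unname(p["t22"]),
      c2 = unname(p["a1"] / tot), t2f2 = unname(p["t21"]))
  }
  out
}

#' Fit the tri-exponential water-T2 model to one decay
#'
#' Nonlinear least squares over water amplitude, fat amplitude and water T2
#' with the fat pair fixed:
#' `S(TE) = A_w exp(-TE/T2w) + A_f (c1 exp(-TE/T2f1) + c2 exp(-TE/T2f2))`.
#' The start value for T2w comes from a log-linear fit, so the fit is
#' deterministic.
#'
#' @param signal region-mean decay (same length as `echo_times`).
#' @param echo_times echo times in ms, at least 8.
#' @param fat_pair fat pair `c(c1, t2f1, c2, t2f2)` from [calibrate_fat_t2()].
#' @param bounds T2w fit bounds in ms.
#' @param pdff_hint optional fat-fraction hint in \[0,1\] for the amplitude
#'   start values.
#' @return One-row tibble: `t2w_ms`, `a_w`, `a_f`, `resid_norm`, `converged`.
#' @export
fit_water_t2 <- function(signal, echo_times, fat_pair,
                         bounds = c(10, 100), pdff_hint = NULL) {
  if (length(echo_times) < 8) abort("water T2 fitting needs >= 8 echoes")
  if (all(is.na(signal))) {
    return(tibble::tibble(t2w_ms = NA_real_, a_w = NA_real_, a_f = NA_real_,
                          resid_norm = NA_real_, converged = FALSE))
  }
  if (!is.finite(signal[1]) || signal[1] <= 0) {
    abort("signal must be positive at the first echo")
  }
  te <- echo_times
  y <- signal
  ffh <- pdff_hint %||% 0.2
  # log-linear init on the early echoes
  early <- te <= stats::quantile(te, 0.5)
  ll <- lm(log(pmax(y[early], 1e-12)) ~ te[early])
  t2_init <- min(max(-1 / coef(ll)[2], bounds[1] + 2), bounds[2] - 2)
  if (!is.finite(t2_init)) t2_init <- 35
  a0 <- exp(coef(ll)[1])
  fat_decay <- fat_pair[["c1"]] * exp(-te / fat_pair[["t2f1"]]) +
    fat_pair[["c2"]] * exp(-te / fat_pair[["t2f2"]])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(aw = max(a0 * (1 - ffh), 1e-6), af = max(a0 * ffh, 1e-6),
              t2w = t2_init),
      lower = c(0, 0, bounds[1]), upper = c(Inf, Inf, bounds[2]),
      fn = function(p) y - (p[1] * exp(-te / p[3]) + p[2] * fat_decay),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(tibble::tibble(t2w_ms = NA_real_, a_w = NA_real_, a_f = NA_real_,
                          resid_norm = NA_real_, converged = FALSE))
  }
  p <- fit$par
  tibble::tibble(t2w_ms = unname(p["t2w"]), a_w = unname(p["aw"]),
                 a_f = unname(p["af"]),
                 resid_norm = sqrt(fit$deviance),
                 converged = TRUE)
}

#' Region-level water T2 for all muscle compartments
#'
#' Calibrates the fat pair on subcutaneous fat, then fits the
#' tri-exponential model to each muscle region's mean decay. Regions whose
#' mean PDFF exceeds the exclusion threshold are not fitted and returned as
#' excluded rows (reason `"pdff_gt_threshold"`).
#'
#' @param mese magnitude [echo_series].
#' @param masks a [region_mask_set] on the MESE grid.
#' @param pdff_table optional tibble from the Dixon stage with columns
#'   `region`, `value` (PDFF in percent); enables the exclusion rule.
#' @param threshold_percent PDFF exclusion threshold (percent).
#' @param fat_pair optional fat pair; default calibrates from `fat_region`.
#' @param fat_region subcutaneous fat region name for calibration.
#' @return Tibble with one row per muscle region: `region`, `parameter`
#'   (`"water_t2"`), `value` (T2w ms), `a_w`, `a_f`, `voxel_count`,
#'   `excluded`, `exclusion_reason`.
#' @export
fit_muscle_t2 <- function(mese, masks, pdff_table = NULL,
                          threshold_percent = 50, fat_pair = NULL,
                          fat_region = "SCF") {
  if (is.null(fat_pair)) fat_pair <- calibrate_fat_t2(mese, masks, fat_region)
  muscles <- masks$label_table[masks$label_table$class == "muscle", ]
  te <- mese$echo_times
  rows <- purrr::map_dfr(seq_len(nrow(muscles)), function(i) {
    nm <- muscles$name[i]
    pd <- NULL
    if (!is.null(pdff_table)) {
      j <- match(nm, pdff_table$region)
      if (is.na(j)) abort(sprintf("no PDFF row for region '%s'", nm))
      pd <- pdff_table$value[j]
    }
    sel <- region_indicator(masks, nm)
    base <- tibble::tibble(region = nm, parameter = "water_t2",
                           voxel_count = sum(sel))
    if (!is.null(pd) && is.finite(pd) && pd > threshold_percent) {
      return(dplyr::mutate(base, value = NA_real_, a_w = NA_real_, a_f = NA_real_,
                           excluded = TRUE, exclusion_reason = "pdff_gt_threshold"))
    }
    y <- vapply(mese$volumes, function(v) mean(v$data[sel], na.rm = TRUE), numeric(1))
    ft <- fit_water_t2(y, te, fat_pair,
                       pdff_hint = if (!is.null(pd)) pd / 100 else NULL)
    dplyr::mutate(base, value = ft$t2w_ms, a_w = ft$a_w, a_f = ft$a_f,
                  excluded = !ft$converged,
                  exclusion_reason = ifelse(ft$converged, "", "fit_failed"))
  })
  attr(rows, "fat_pair") <- fat_pair
  rows
}

#' Apply the PDFF exclusion rule to a parameter table
#'
#' Rows whose region-mean PDFF exceeds the threshold are flagged excluded
#' for all downstream quantitative parameters (PDFF itself is never
#' excluded by this rule). The rule is idempotent.
#'
#' @param table parameter tibble with `region` (and optionally `subject_id`)
#'   and `value` columns.
#' @param pdff_table PDFF tibble with matching keys and `value` in percent.
#' @param threshold_percent exclusion threshold, default 50 (percent PDFF).
#' @return `table` with `excluded` / `exclusion_reason` updated.
#' @export
apply_exclusions <- function(table, pdff_table, threshold_percent = 50) {
  keys <- intersect(c("subject_id", "region"), intersect(names(table), names(pdff_table)))
  if (!"region" %in% keys) abort("tables must share a 'region' key")
  pd <- dplyr::select(pdff_table, dplyr::all_of(keys), pdff_pct = "value")
  out <- dplyr::left_join(table, pd, by = keys)
  missing <- !stats::complete.cases(out["pdff_pct"])
  if (any(missing)) {
    k <- out[missing, keys, drop = FALSE]
    abort(sprintf("no PDFF value for key(s): %s",
                  paste(apply(k, 1, paste, collapse = "/"), collapse = ", ")))
  }
  if (!"excluded" %in% names(out)) out$excluded <- FALSE
  if (!"exclusion_reason" %in% names(out)) out$exclusion_reason <- ""
  hit <- out$pdff_pct > threshold_percent
  out$excluded <- out$excluded | hit
  out$exclusion_reason <- ifelse(hit & out$exclusion_reason == "",
                                 "pdff_gt_threshold", out$exclusion_reason)
  dplyr::select(out, -"pdff_pct")
}
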