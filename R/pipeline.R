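# End-to-end orchestration: per-subject processing of the four
# acquisitions, cohort-level fat correction and relative IR, group
# statistics, extracellular-volume inversion, and the disk-based study
# layout (NIfTI volumes + label side-cars + YAML config + TSV tables).

#' Default pipeline constants
#'
#' All tunable constants of the quantification chain in one list: the fat
#' correction constants, the PDFF exclusion threshold (percent), serum ion
#' concentrations (mM) and healthy extracellular volume fraction for the
#' two-compartment inversion, the per-class relaxation factors, the
#' X-nuclei PSF FWHM (mm) and the calibration intercept switch.
#' @export
pipeline_constants <- function() {
  fc <- fat_correction_constants()
  list(
    pdff_exclusion_percent = fc$pdff_exclusion_percent,
    atsc_fat = fc$atsc_fat, atpc_fat = fc$atpc_fat, ir_fat = fc$ir_fat,
    serum_na = 140, serum_k = 4.2, ve0 = 0.07,
    relaxation_factors = as.list(default_relaxation_factors()),
    psf_fwhm_mm = 15,
    calibration_intercept = TRUE
  )
}

#' Process one subject's acquisitions into a long region table
#'
#' Runs the Dixon fit (field map, water/fat separation, PDFF), the
#' tri-exponential water-T2 fit with the PDFF exclusion rule, and the
#' sodium/IR/potassium quantification chain (PVC, relaxation correction,
#' tube calibration), and returns everything as one long tibble.
#'
#' @param subj a subject list as produced by [simulate_subject()] (fields
#'   `masks`, `dixon`, `mese`, `na`, `na_ir`, `k`), plus optional `id`.
#' @param constants see [pipeline_constants()].
#' @return Long tibble keyed by (`subject_id`, `region`, `parameter`) with
#'   `value`, `dispersion`, `voxel_count`, `excluded`, `exclusion_reason`;
#'   calibration models are attached as attribute `calibrations`.
#' @export
process_subject <- function(subj, constants = pipeline_constants()) {
  id <- subj$id %||% "S01"
  masks_h1 <- subj$masks$h1
  masks_xn <- subj$masks$xn
  thr <- constants$pdff_exclusion_percent

  fw <- fit_dixon(subj$dixon)
  pdff_rows <- region_means(fw$pdff, masks_h1)
  pdff_rows <- dplyr::filter(pdff_rows, .data$class %in% c("muscle", "subcutaneous_fat"))
  pdff_rows <- dplyr::mutate(pdff_rows, value = 100 * .data$value,
                             dispersion = 100 * .data$dispersion,
                             parameter = "pdff")
  pdff_muscle <- dplyr::filter(pdff_rows, .data$class == "muscle")

  t2_rows <- fit_muscle_t2(subj$mese, masks_h1, pdff_table = pdff_muscle,
                           threshold_percent = thr)
  t2_rows <- dplyr::mutate(t2_rows, dispersion = NA_real_)

  psf <- psf_spec("gaussian", constants$psf_fwhm_mm)
  factors <- unlist(constants$relaxation_factors)
  calibs <- list()
  ion_rows <- purrr::map_dfr(c("na", "na_ir", "k"), function(nuc) {
    q <- quantify_xnuclei(subj[[nuc]], masks_xn, psf, factors = factors,
                          intercept = constants$calibration_intercept)
    calibs[[nuc]] <<- attr(q, "calibration")
    q <- dplyr::filter(q, .data$class == "muscle")
    q <- apply_exclusions(q, pdff_muscle, threshold_percent = thr)
    dplyr::mutate(q, dispersion = NA_real_)
  })

  out <- dplyr::bind_rows(
    dplyr::select(pdff_rows, "region", "class", "parameter", "value",
                  "dispersion", "voxel_count", "excluded", "exclusion_reason"),
    dplyr::mutate(dplyr::select(t2_rows, "region", "parameter", "value",
                                "dispersion", "voxel_count", "excluded",
                                "exclusion_reason"), class = "muscle"),
    dplyr::select(ion_rows, "region", "class", "parameter", "value",
                  "dispersion", "voxel_count", "excluded", "exclusion_reason")
  )
  out <- dplyr::mutate(out, subject_id = id, .before = 1)
  attr(out, "calibrations") <- calibs
  attr(out, "fat_pair") <- attr(t2_rows, "fat_pair")
  out
}

#' Process a whole study: per-subject tables, corrections, statistics
#'
#' Processes every subject with [process_subject()], fat-corrects the ion
#' parameters with the subject's muscle PDFF, computes relative IR against
#' the control regression, runs group comparisons with the DAP adjustment
#' for every quantitative parameter, and inverts the two-compartment model
#' for the group-mean fat-corrected concentrations.
#'
#' @param study an `xmuscle_study` (see [simulate_cohort_study()]) or a
#'   list with `subjects` and `control_group`.
#' @param constants see [pipeline_constants()].
#' @param progress print one line per subject.
#' @return List of tibbles: `regions` (long per-subject table with
#'   fat-corrected values), `group_stats`, `ecv`, `calibrations`,
#'   `exclusions`.
#' @export
process_study <- function(study, constants = pipeline_constants(),
                          progress = FALSE) {
  groups <- vapply(study$subjects, `[[`, character(1), "group")
  tabs <- purrr::map2(study$subjects, groups, function(s, g) {
    if (progress) message("processing subject ", s$id)
    dplyr::mutate(process_subject(s, constants), group = g)
  })
  calib_rows <- purrr::map_dfr(seq_along(tabs), function(i) {
    cl <- attr(tabs[[i]], "calibrations")
    purrr::map_dfr(names(cl), function(nuc) {
      m <- cl[[nuc]]
      if (is.null(m)) return(NULL)
      tibble::tibble(subject_id = study$subjects[[i]]$id, nucleus = nuc,
                     slope = m$slope, intercept = m$intercept,
                     r_squared = m$r_squared, n_points = m$n_points)
    })
  })
  long <- dplyr::bind_rows(tabs)

  # attach each subject's muscle PDFF (fraction) to the ion rows
  pdff <- dplyr::filter(long, .data$parameter == "pdff", .data$class == "muscle")
  pdff <- dplyr::select(pdff, "subject_id", "region", pdff_pct = "value")
  wide_keys <- c("subject_id", "region")
  ion <- dplyr::left_join(
    dplyr::filter(long, .data$parameter %in% c("atsc", "atpc", "ir")),
    pdff, by = wide_keys)
  fatc <- c(atsc = constants$atsc_fat, atpc = constants$atpc_fat,
            ir = constants$ir_fat)
  ion <- dplyr::group_by(ion, .data$parameter)
  ion <- dplyr::group_modify(ion, function(d, key) {
    d$pdff_frac <- d$pdff_pct / 100
    d$value_masked <- ifelse(d$excluded, NA_real_, d$value)
    fat_correct(d, "value_masked", "pdff_frac", fatc[[key$parameter]],
                threshold_percent = constants$pdff_exclusion_percent)
  })
  ion <- dplyr::ungroup(ion)
  ion <- dplyr::select(ion, -"value_masked", -"pdff_frac")

  # relative IR against the control regression
  ir_fc <- dplyr::filter(ion, .data$parameter == "ir")
  na_fc <- dplyr::filter(ion, .data$parameter == "atsc")
  both <- dplyr::inner_join(
    dplyr::select(ir_fc, "subject_id", "group", "region", ir_fc = "value_fc"),
    dplyr::select(na_fc, "subject_id", "region", atsc_fc = "value_fc"),
    by = wide_keys)
  ctl_ids <- unique(long$subject_id[long$group == study$control_group])
  rel <- relative_ir(both, "ir_fc", "atsc_fc", "subject_id", ctl_ids)
  rel_rows <- dplyr::transmute(
    rel, subject_id = .data$subject_id, group = .data$group,
    region = .data$region, class = "muscle", parameter = "relative_ir",
    value = .data$relative_ir, value_fc = .data$relative_ir,
    excluded = !is.finite(.data$relative_ir),
    exclusion_reason = ifelse(is.finite(.data$relative_ir), "", "missing_input"))

  regions <- dplyr::bind_rows(
    dplyr::filter(long, .data$parameter %in% c("pdff", "water_t2")),
    ion, rel_rows)

  # group comparisons per parameter over muscle endpoints
  stat_input <- dplyr::bind_rows(
    dplyr::transmute(
      dplyr::filter(regions, .data$parameter %in% c("pdff", "water_t2"),
                    .data$class == "muscle"),
      subject_id = .data$subject_id, group = .data$group, region = .data$region,
      parameter = .data$parameter,
      value = ifelse(.data$excluded, NA_real_, .data$value)),
    dplyr::transmute(
      dplyr::filter(regions, .data$parameter %in% c("atsc", "atpc", "ir")),
      subject_id = .data$subject_id, group = .data$group, region = .data$region,
      parameter = paste0(.data$parameter, "_fc"),
      value = ifelse(.data$excluded, NA_real_, .data$value_fc)),
    dplyr::transmute(
      dplyr::filter(regions, .data$parameter == "relative_ir"),
      subject_id = .data$subject_id, group = .data$group, region = .data$region,
      parameter = .data$parameter,
      value = ifelse(.data$excluded, NA_real_, .data$value))
  )
  group_stats <- stat_input |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(d, key) {
      compare_endpoints(d, value, region, subject_id, group)
    }) |>
    dplyr::ungroup()

  ecv <- study_ecv(regions, study$control_group, constants)

  exclusions <- dplyr::filter(regions, .data$excluded)
  list(regions = regions, group_stats = group_stats, ecv = ecv,
       calibrations = calib_rows,
       exclusions = dplyr::select(exclusions, "subject_id", "region",
                                  "parameter", "exclusion_reason"))
}

#' Two-compartment ECV inversion of the study's group means
#'
#' From the fat-corrected group-mean aTSC/aTPC of controls and patients,
#' infers the intracellular concentration at the healthy extracellular
#' volume fraction and the extracellular volume fraction that would explain
#' the patient group mean on its own.
#'
#' @param regions long region table from [process_study()].
#' @param control_group control group label.
#' @param constants see [pipeline_constants()].
#' @return Tibble per ion: group means, inferred `c_i`, and `ve_patient`.
#' @export
study_ecv <- function(regions, control_group = "control",
                      constants = pipeline_constants()) {
  purrr::map_dfr(c(atsc = "atsc", atpc = "atpc"), function(par) {
    d <- dplyr::filter(regions, .data$parameter == par, !.data$excluded,
                       is.finite(.data$value_fc))
    if (!nrow(d)) return(NULL)
    is_ctl <- d$group == control_group
    m_ctl <- mean(d$value_fc[is_ctl])
    m_pat <- mean(d$value_fc[!is_ctl])
    c_e <- if (par == "atsc") constants$serum_na else constants$serum_k
    c_i <- infer_intracellular(m_ctl, constants$ve0, c_e)
    ve <- ecv_from_concentration(m_pat, two_compartment_model(c_i, c_e))
    tibble::tibble(parameter = par, control_mean = m_ctl, patient_mean = m_pat,
                   c_e = c_e, c_i = c_i, ve0 = constants$ve0,
                   ve_patient = ve$ve_raw)
  })
}

#' Write a simulated study to disk
#'
#' Emits, per subject, the Dixon echo pairs, the MESE echoes, the three
#' X-nuclei volumes, the label maps with their TSV side-cars, and a
#' `truth.tsv`; plus a `study.yaml` the pipeline can run from.
#'
#' @param study an `xmuscle_study`.
#' @param out_dir output directory.
#' @param constants pipeline constants recorded into the config.
#' @return Path of the written `study.yaml`, invisibly.
#' @export
simulate_study <- function(study, out_dir, constants = pipeline_constants()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subj_cfg <- lapply(study$subjects, function(s) {
    sd <- file.path(out_dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_echo_series(s$dixon, sd, "dixon")
    write_echo_series(s$mese, sd, "mese")
    for (nuc in c("na", "na_ir", "k")) {
      write_volume(s[[nuc]], file.path(sd, paste0(nuc, ".nii.gz")))
    }
    write_mask_set(s$masks$h1, file.path(sd, "labels_h1.nii.gz"),
                   file.path(sd, "labels_h1.tsv"))
    write_mask_set(s$masks$xn, file.path(sd, "labels_xn.nii.gz"),
                   file.path(sd, "labels_xn.tsv"))
    readr::write_tsv(s$truth$regions, file.path(sd, "truth.tsv"))
    list(id = s$id, group = s$group, dir = s$id)
  })
  cfg <- list(subjects = subj_cfg, control_group = study$control_group,
              constants = constants)
  path <- file.path(out_dir, "study.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

read_study <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  if (is.null(cfg$subjects) || !length(cfg$subjects)) {
    abort("configuration error: no subjects defined")
  }
  subjects <- lapply(cfg$subjects, function(sc) {
    for (f in c("id", "group", "dir")) {
      if (is.null(sc[[f]])) abort(sprintf("configuration error: subject missing '%s'", f))
    }
    sd <- file.path(base, sc$dir)
    needed <- c("na.nii.gz", "na_ir.nii.gz", "k.nii.gz",
                "labels_h1.nii.gz", "labels_h1.tsv",
                "labels_xn.nii.gz", "labels_xn.tsv",
                "dixon_echo_times.tsv", "mese_echo_times.tsv")
    missing <- needed[!file.exists(file.path(sd, needed))]
    if (length(missing)) {
      abort(sprintf("configuration error: subject %s missing inputs: %s",
                    sc$id, paste(missing, collapse = ", ")))
    }
    masks_xn <- read_mask_set(file.path(sd, "labels_xn.nii.gz"),
                              file.path(sd, "labels_xn.tsv"))
    tubes <- masks_xn$label_table$class == "reference_tube"
    if (sum(tubes) < 2 ||
        any(!is.finite(masks_xn$label_table$na_mM[tubes])) ||
        any(!is.finite(masks_xn$label_table$k_mM[tubes]))) {
      abort(sprintf(
        "configuration error: subject %s lacks reference-tube concentrations", sc$id))
    }
    list(id = sc$id, group = sc$group,
         masks = list(h1 = read_mask_set(file.path(sd, "labels_h1.nii.gz"),
                                         file.path(sd, "labels_h1.tsv")),
                      xn = masks_xn),
         dixon = read_echo_series(sd, "dixon", "dixon_echo"),
         mese = read_echo_series(sd, "mese", "mese_echo"),
         na = read_volume(file.path(sd, "na.nii.gz"), "na"),
         na_ir = read_volume(file.path(sd, "na_ir.nii.gz"), "na_ir"),
         k = read_volume(file.path(sd, "k.nii.gz"), "k"))
  })
  constants <- utils::modifyList(pipeline_constants(), cfg$constants %||% list())
  structure(list(subjects = subjects,
                 control_group = cfg$control_group %||% "control",
                 constants = constants),
            class = "xmuscle_study")
}

#' Run the full pipeline from a study configuration
#'
#' Reads a `study.yaml` (as written by [simulate_study()]), validates that
#' every stage input exists before any computation starts, processes all
#' subjects, and writes the region tables, group statistics, calibration
#' report, ECV table and an exclusion log as TSV/plain text into `out_dir`.
#' Deterministic for fixed inputs: the only stochastic component (the
#' Lilliefors null) uses a fixed internal seed.
#'
#' @param config_path path to the YAML study configuration.
#' @param out_dir output directory for tables; defaults to
#'   `<config dir>/results`.
#' @param progress print progress lines.
#' @return The [process_study()] result, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, progress = FALSE) {
  study <- read_study(config_path)
  out_dir <- out_dir %||% file.path(dirname(config_path), "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- process_study(study, constants = study$constants, progress = progress)
  num_cols <- function(d) dplyr::mutate(d, dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 10)))
  readr::write_tsv(num_cols(res$regions), file.path(out_dir, "regions.tsv"))
  readr::write_tsv(num_cols(res$group_stats), file.path(out_dir, "group_stats.tsv"))
  readr::write_tsv(num_cols(res$ecv), file.path(out_dir, "ecv.tsv"))
  readr::write_tsv(num_cols(res$calibrations), file.path(out_dir, "calibrations.tsv"))
  writeLines(
    c(sprintf("exclusions: %d rows", nrow(res$exclusions)),
      sprintf("%s | %s | %s | %s", res$exclusions$subject_id,
              res$exclusions$region, res$exclusions$parameter,
              res$exclusions$exclusion_reason)),
    file.path(out_dir, "exclusions.log"))
  invisible(res)
}
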