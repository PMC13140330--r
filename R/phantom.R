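#' Ground-truth parameter set for the digital leg phantom
#'
#' Bundles everything the generator needs: a per-region parameter table, the
#' cross-section geometry (ellipses in mm), the two acquisition grids (the
#' high-resolution proton grid and the coarse X-nuclei grid), the fat T2
#' pair used by the MESE forward model, and the fat-signal constants shared
#' with the correction stage.
#'
#' The default regions describe a healthy lower leg: seven muscle
#' compartments (GM, GL, SOL, TA, TP, PER, EDL), a subcutaneous fat ring,
#' tibia/fibula marrow discs, and a five-tube NaCl/KCl reference holder
#' below the leg at \[Na+\]/\[K+\] = 10/240, 20/210, 25/180, 30/150 and
#' 40/120 mM.
#'
#' @param regions per-region parameter tibble; see [phantom_regions()].
#' @param geometry ellipse geometry tibble; see [phantom_geometry()].
#' @param h1_dims,h1_voxel proton grid shape and voxel size (mm).
#' @param xn_dims,xn_voxel X-nuclei grid shape and voxel size (mm).
#' @param fat_t2 MESE fat pair: named vector `c(c1, t2f1, c2, t2f2)` with
#'   amplitude fractions summing to 1 and T2s in ms.
#' @param fat_constants a [fat_correction_constants()] list.
#' @param ir_gain,ir_offset a.u. per mM and a.u.; map a region's sodium
#'   concentration and inversion-recovery weighting factor to its IR signal.
#' @return A `phantom_truth` object.
#' @export
phantom_truth <- function(regions = phantom_regions("control"),
                          geometry = phantom_geometry(),
                          h1_dims = c(64L, 80L, 3L), h1_voxel = c(2.5, 2.5, 6),
                          xn_dims = c(16L, 20L, 3L), xn_voxel = c(10, 10, 6),
                          fat_t2 = c(c1 = 0.55, t2f1 = 45, c2 = 0.45, t2f2 = 170),
                          fat_constants = fat_correction_constants(),
                          ir_gain = 0.08, ir_offset = 0.3) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(regions$fat_fraction >= 0 & regions$fat_fraction <= 1),
            all(regions$na_mM >= 0), all(regions$k_mM >= 0))
  miss <- setdiff(regions$name, geometry$name)
  if (length(miss)) abort(sprintf("regions without geometry: %s", paste(miss, collapse = ", ")))
  structure(list(regions = regions, geometry = tibble::as_tibble(geometry),
                 h1_dims = as.integer(h1_dims), h1_voxel = h1_voxel,
                 xn_dims = as.integer(xn_dims), xn_voxel = xn_voxel,
                 fat_t2 = fat_t2, fat_constants = fat_constants,
                 ir_gain = ir_gain, ir_offset = ir_offset),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d regions; 1H grid %s @ %s mm; X grid %s @ %s mm\n",
              nrow(x$regions), paste(x$h1_dims, collapse = "x"),
              paste(x$h1_voxel, collapse = "x"),
              paste(x$xn_dims, collapse = "x"),
              paste(x$xn_voxel, collapse = "x")))
  print(x$regions)
  invisible(x)
}

#' Per-region phantom parameters for the cohort presets
#'
#' `"control"` emulates healthy muscle (fat fraction 0.03-0.08, tissue
#' sodium 23 mM, potassium 109 mM); `"mfm"` emulates a myofibrillar-myopathy
#' pattern with strong, muscle-dependent fatty replacement (fat fraction
#' 0.1-0.9, highest in soleus/medial gastrocnemius, lowest in lateral
#' gastrocnemius), elevated remaining-muscle sodium (55.6 mM), reduced
#' potassium (75.4 mM) and prolonged water T2.
#'
#' @param preset `"control"` or `"mfm"`.
#' @return Tibble with one row per region: `name`, `class`, `amp` (relative
#'   proton signal), `fat_fraction`, `water_t2` ms, `na_mM`, `k_mM`,
#'   `ir_factor` (intracellular weighting multiplier), `field_offset_hz`,
#'   `r2star` (1/s).
#' @export
phantom_regions <- function(preset = c("control", "mfm")) {
  preset <- match.arg(preset)
  m <- tibble::tibble(
    name = MUSCLE_NAMES,
    class = "muscle", amp = 1,
    fat_fraction = switch(preset,
      control = c(0.05, 0.04, 0.06, 0.05, 0.04, 0.06, 0.05),
      mfm     = c(0.65, 0.15, 0.75, 0.35, 0.30, 0.55, 0.45)),
    water_t2 = switch(preset,
      control = c(31, 31.5, 32, 31, 30.5, 31.5, 31),
      mfm     = c(42, 38, 44, 33, 33, 40, 41)),
    na_mM = switch(preset, control = 23, mfm = 55.6),
    k_mM = switch(preset, control = 109, mfm = 75.4),
    ir_factor = 1,
    field_offset_hz = c(10, -15, 5, 20, -5, 15, -20),
    r2star = 35
  )
  other <- tibble::tibble(
    name = c("SCF", "TIB", "FIB", paste0("TUBE", 1:5)),
    class = c("subcutaneous_fat", "bone", "bone", rep("reference_tube", 5)),
    amp = c(1, 0.25, 0.25, rep(1, 5)),
    fat_fraction = c(0.90, 0.80, 0.80, rep(0, 5)),
    water_t2 = c(40, 40, 40, rep(600, 5)),
    na_mM = c(7.9, 0, 0, 10, 20, 25, 30, 40),
    k_mM = c(0, 0, 0, 240, 210, 180, 150, 120),
    ir_factor = c(1, 1, 1, rep(0.1, 5)),
    field_offset_hz = c(0, 0, 0, rep(0, 5)),
    r2star = c(45, 60, 60, rep(5, 5))
  )
  dplyr::bind_rows(m, other)
}

#' Cross-section geometry of the leg phantom
#'
#' Ellipses in world mm on a 160 x 200 mm field of view: the outer leg
#' contour (filled with subcutaneous fat outside the muscles), the seven
#' muscle compartments, two bone discs, and the reference-tube holder strip
#' below the leg.
#'
#' @param tube_radius_mm radius of the five reference tubes.
#' @return Tibble with columns `name`, `cx`, `cy`, `a`, `b` (mm).
#' @export
phantom_geometry <- function(tube_radius_mm = 12) {
  r <- tube_radius_mm
  tibble::tribble(
    ~name,   ~cx, ~cy, ~a, ~b,
    "GM",     60,  85, 17, 14,
    "GL",     99,  87, 15, 12,
    "SOL",    80, 110, 32, 10,
    "TA",     60, 154, 13, 13,
    "TP",     86, 133, 10,  7,
    "PER",   107, 143,  9, 12,
    "EDL",    84, 157, 11, 11,
    "TIB",    62, 130,  9,  9,
    "FIB",   107, 123, 5.5, 5.5,
    "SCF",    80, 121, 55, 62,   # outer leg contour; fat fills non-muscle
    "TUBE1",  20,  25,  r,  r,
    "TUBE2",  50,  25,  r,  r,
    "TUBE3",  80,  25,  r,  r,
    "TUBE4", 110,  25,  r,  r,
    "TUBE5", 140,  25,  r,  r
  )
}

# affine placing voxel centres at (i + 1/2) * voxel, i 0-based
centered_affine <- function(voxel) {
  a <- diag(c(voxel, 1))
  a[1:3, 4] <- voxel / 2
  a
}

#' Rasterise the leg phantom onto both acquisition grids
#'
#' Paints the regions of [phantom_truth()] onto the proton and X-nuclei
#' grids. Muscles and bones are painted first in table order (on contested
#' voxels the earlier region wins and a warning is logged), the outer leg
#' ellipse then fills every remaining interior voxel as subcutaneous fat,
#' and the reference tubes are painted below the leg.
#'
#' @param truth a [phantom_truth()].
#' @return List with elements `h1` and `xn`, each a [region_mask_set] whose
#'   label table carries the nominal tube concentrations.
#' @export
build_leg_phantom <- function(truth) {
  list(h1 = rasterise_grid(truth, truth$h1_dims, truth$h1_voxel),
       xn = rasterise_grid(truth, truth$xn_dims, truth$xn_voxel))
}

rasterise_grid <- function(truth, dims, voxel) {
  aff <- centered_affine(voxel)
  xyz <- voxel_to_world(aff, voxel_grid(dims))
  geo <- truth$geometry
  reg <- truth$regions
  # label ids follow region-table order
  lab_tab <- tibble::tibble(label = seq_len(nrow(reg)), name = reg$name,
                            class = reg$class,
                            na_mM = ifelse(reg$class == "reference_tube", reg$na_mM, NA_real_),
                            k_mM = ifelse(reg$class == "reference_tube", reg$k_mM, NA_real_))
  lab <- integer(nrow(xyz))
  inside <- function(nm) {
    g <- geo[geo$name == nm, ]
    if (nrow(g) != 1) abort(sprintf("no geometry for region '%s'", nm))
    ((xyz[, 1] - g$cx) / g$a)^2 + ((xyz[, 2] - g$cy) / g$b)^2 <= 1
  }
  solid <- reg$name[reg$class %in% c("muscle", "bone", "reference_tube")]
  for (nm in solid) {
    sel <- inside(nm)
    contested <- sel & lab != 0L
    if (any(contested)) {
      warn(sprintf("region '%s' loses %d contested voxels to earlier regions",
                   nm, sum(contested)))
    }
    lab[sel & lab == 0L] <- lab_tab$label[lab_tab$name == nm]
  }
  fat_nm <- reg$name[reg$class == "subcutaneous_fat"]
  if (length(fat_nm) == 1) {
    sel <- inside(fat_nm) & lab == 0L
    lab[sel] <- lab_tab$label[lab_tab$name == fat_nm]
  }
  map <- volume_image(array(lab, dims), voxel_size = voxel, affine = aff,
                      modality_tag = "label")
  region_mask_set(map, lab_tab)
}

# per-voxel lookup of a region parameter; 'default' outside any region
region_param_map <- function(masks, regions, param, default = 0) {
  idx <- match(as.vector(masks$label_map$data), masks$label_table$label)
  ord <- match(masks$label_table$name, regions$name)
  vals <- regions[[param]][ord][idx]
  vals[is.na(idx)] <- default
  vals[is.na(vals)] <- default
  vals
}
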