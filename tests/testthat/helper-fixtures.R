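# Shared fixtures: small grids and reduced phantoms so the suite stays fast.

# single-slice study grids covering the same 160 x 200 mm field of view
small_truth_args <- function() {
  list(h1_dims = c(48L, 60L, 1L), h1_voxel = c(10 / 3, 10 / 3, 6),
       xn_dims = c(16L, 20L, 1L), xn_voxel = c(10, 10, 6))
}

# a one-region phantom: a single muscle disc in a small grid, no fat ring
uniform_disc_truth <- function(ff = 0.4, psi = 0, r2star = 40, t2w = 31,
                               na = 23, k = 109, dims = c(24L, 24L, 1L),
                               voxel = c(3, 3, 6)) {
  reg <- tibble::tibble(name = "SOL", class = "muscle", amp = 1,
                        fat_fraction = ff, water_t2 = t2w, na_mM = na,
                        k_mM = k, ir_factor = 1, field_offset_hz = psi,
                        r2star = r2star)
  geo <- tibble::tibble(name = "SOL", cx = dims[1] * voxel[1] / 2,
                        cy = dims[2] * voxel[2] / 2,
                        a = dims[1] * voxel[1] * 0.35,
                        b = dims[2] * voxel[2] * 0.35)
  phantom_truth(regions = reg, geometry = geo, h1_dims = dims,
                h1_voxel = voxel, xn_dims = dims, xn_voxel = voxel)
}

# independent 3D Gaussian blur: explicit shift-and-add convolution over the
# full separable kernel support (oracle for the GTM tests)
oracle_blur3d <- function(arr, fwhm_mm, voxel_size) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  k1 <- lapply(1:3, function(ax) {
    sigma <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / voxel_size[ax]
    if (sigma < 1e-6) return(1)
    half <- max(1L, ceiling(5 * sigma))
    x <- (-half):half
    k <- pnorm((x + 0.5) / sigma) - pnorm((x - 0.5) / sigma)
    k / sum(k)
  })
  d <- dim(arr)
  out <- array(0, d)
  h <- vapply(k1, function(k) (length(k) - 1L) / 2L, numeric(1))
  for (i in seq_along(k1[[1]])) for (j in seq_along(k1[[2]])) for (l in seq_along(k1[[3]])) {
    w <- k1[[1]][i] * k1[[2]][j] * k1[[3]][l]
    di <- i - 1L - h[1]; dj <- j - 1L - h[2]; dl <- l - 1L - h[3]
    xs <- intersect(seq_len(d[1]), seq_len(d[1]) - di)
    ys <- intersect(seq_len(d[2]), seq_len(d[2]) - dj)
    zs <- intersect(seq_len(d[3]), seq_len(d[3]) - dl)
    if (!length(xs) || !length(ys) || !length(zs)) next
    out[xs, ys, zs] <- out[xs, ys, zs] + w * arr[xs + di, ys + dj, zs + dl]
  }
  out
}

# random multi-region box phantom on a small grid for PVC oracle tests
random_box_masks <- function(n_regions = 4, dims = c(20L, 20L, 8L),
                             voxel = c(4, 4, 4)) {
  lab <- array(0L, dims)
  for (r in seq_len(n_regions)) {
    sz <- pmin(sample(3:6, 3, replace = TRUE), dims - 2L)
    lo <- c(sample(seq_len(dims[1] - sz[1]), 1), sample(seq_len(dims[2] - sz[2]), 1),
            sample(seq_len(dims[3] - sz[3]), 1))
    sel <- lab[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]), lo[3]:(lo[3] + sz[3])]
    sel[sel == 0L] <- r
    lab[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]), lo[3]:(lo[3] + sz[3])] <- sel
  }
  # ensure every region has at least one voxel
  for (r in seq_len(n_regions)) if (!any(lab == r)) lab[r, 1, 1] <- r
  map <- volume_image(lab, voxel_size = voxel, modality_tag = "label")
  region_mask_set(map, tibble::tibble(
    label = seq_len(n_regions), name = paste0("R", seq_len(n_regions)),
    class = "muscle"))
}

# closed-form Dixon signal for one voxel (independent of the package model)
hand_dixon_signal <- function(te_ms, ff, psi_hz, r2star, spectrum) {
  te <- te_ms / 1000
  vapply(te, function(t) {
    fat <- sum(spectrum$amplitude * exp(2i * pi * spectrum$freq_hz * t))
    ((1 - ff) + ff * fat) * exp(2i * pi * psi_hz * t) * exp(-r2star * t)
  }, complex(1))
}

# one scaled study replicate: simulate a two-group cohort on single-slice
# grids, run the full pipeline, and summarise recovery + inference
cohort_replicate <- function(seed, n_control = 10, n_mfm = 9) {
  st <- simulate_cohort_study(n_control, n_mfm, seed = seed,
                              truth_args = small_truth_args())
  res <- process_study(st)
  truth <- purrr::map_dfr(st$subjects, function(s) {
    d <- s$truth$regions[s$truth$regions$class == "muscle", ]
    tibble::tibble(subject_id = s$id, group = s$group, region = d$name,
                   na_true = d$na_mM, k_true = d$k_mM)
  })
  rec <- dplyr::inner_join(
    dplyr::filter(res$regions, parameter %in% c("atsc", "atpc"), !excluded,
                  is.finite(value_fc)),
    truth, by = c("subject_id", "region"))
  rec$true_value <- ifelse(rec$parameter == "atsc", rec$na_true, rec$k_true)
  means <- rec |>
    dplyr::group_by(parameter, group.x) |>
    dplyr::summarise(est = mean(value_fc), truth = mean(true_value),
                     .groups = "drop")
  gs <- dplyr::filter(res$group_stats, parameter %in% c("atsc_fc", "atpc_fc"),
                      !is.na(p_adjusted))
  majority <- gs |>
    dplyr::group_by(parameter) |>
    dplyr::summarise(frac_sig = mean(p_adjusted < 0.05), .groups = "drop")
  list(means = means, majority = majority, res = res)
}
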