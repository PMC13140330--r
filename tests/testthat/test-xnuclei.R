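test_that("region PVC with a delta PSF is the identity", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  img <- synthesize_xnuclei(tr, m$xn, "na", psf = psf_spec("delta"))
  pvc <- region_pvc(img, m$xn, psf_spec("delta"))
  expect_equal(pvc$gtm, diag(nrow(pvc$gtm)), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pvc$values$corrected, pvc$values$observed, tolerance = 1e-12)
})

test_that("two-slab PVC recovers true values via the brute-force GTM oracle", {
  dims <- c(32L, 32L, 1L); voxel <- c(2, 2, 2)
  lab <- array(0L, dims)
  lab[6:16, 8:24, 1] <- 1L
  lab[17:27, 8:24, 1] <- 2L
  masks <- region_mask_set(
    volume_image(lab, voxel_size = voxel, modality_tag = "label"),
    tibble::tibble(label = 1:2, name = c("A", "B"), class = "muscle"))
  truth <- c(10, 40)
  ideal <- array(0, dims); ideal[lab == 1L] <- 10; ideal[lab == 2L] <- 40
  psf <- psf_spec("gaussian", fwhm_mm = 4)  # 2 voxels
  img <- volume_image(oracle_blur3d(ideal, psf$fwhm_mm, voxel), voxel_size = voxel)
  pvc <- region_pvc(img, masks, psf)
  est <- pvc$values$corrected[match(c("A", "B"), pvc$values$region)]
  expect_equal(est, truth, tolerance = 1e-6)

  # explicit pseudo-inverse of a brute-force-assembled GTM
  supports <- list(lab == 1L, lab == 2L, lab == 0L)
  M <- sapply(supports, function(sj) {
    bj <- oracle_blur3d(array(as.numeric(sj), dims), psf$fwhm_mm, voxel)
    vapply(supports, function(si) mean(bj[si]), numeric(1))
  })
  b <- vapply(supports, function(si) mean(img$data[si]), numeric(1))
  s_oracle <- solve(crossprod(M), crossprod(M, b))
  expect_equal(pvc$values$corrected, as.vector(s_oracle), tolerance = 1e-6)
})

test_that("PVC equals the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:5) {
    masks <- random_box_masks(n_regions = sample(3:5, 1))
    dims <- dim(masks$label_map$data)
    voxel <- masks$label_map$voxel_size
    vals <- stats::runif(nrow(masks$label_table), 5, 50)
    ideal <- array(0, dims)
    for (r in seq_len(nrow(masks$label_table))) {
      ideal[masks$label_map$data == masks$label_table$label[r]] <- vals[r]
    }
    psf <- psf_spec("gaussian", fwhm_mm = 6)
    img <- volume_image(oracle_blur3d(ideal, psf$fwhm_mm, voxel), voxel_size = voxel)
    pvc <- region_pvc(img, masks, psf)
    lab <- masks$label_map$data
    supports <- c(lapply(masks$label_table$label, function(l) lab == l),
                  list(lab == 0L))
    M <- sapply(supports, function(sj) {
      bj <- oracle_blur3d(array(as.numeric(sj), dims), psf$fwhm_mm, voxel)
      vapply(supports, function(si) mean(bj[si]), numeric(1))
    })
    b <- vapply(supports, function(si) mean(img$data[si]), numeric(1))
    s_oracle <- solve(crossprod(M), crossprod(M, b))
    expect_equal(pvc$values$corrected, as.vector(s_oracle), tolerance = 1e-6)
    nreg <- nrow(masks$label_table)
    expect_equal(pvc$values$corrected[seq_len(nreg)], vals, tolerance = 1e-6)
  }
})

test_that("a region engulfed by the blur raises the condition-number flag", {
  dims <- c(16L, 16L, 1L); voxel <- c(2, 2, 2)
  lab <- array(0L, dims)
  lab[8, 8, 1] <- 1L           # single voxel
  lab[2:5, 2:5, 1] <- 2L
  masks <- region_mask_set(
    volume_image(lab, voxel_size = voxel, modality_tag = "label"),
    tibble::tibble(label = 1:2, name = c("dot", "box"), class = "muscle"))
  img <- volume_image(array(1, dims), voxel_size = voxel)
  expect_warning(pvc <- region_pvc(img, masks, psf_spec("gaussian", 30),
                                   condition_limit = 100), "condition")
  expect_true(pvc$flagged)
})

test_that("relaxation correction divides by class factors and checks inputs", {
  vals <- tibble::tibble(region = c("GM", "SCF", "T1", ".background"),
                         class = c("muscle", "subcutaneous_fat",
                                   "reference_tube", "background"),
                         observed = c(8, 6, 9.5, 0), corrected = c(8, 6, 9.5, 0),
                         voxel_count = c(10, 10, 5, 100))
  out1 <- relaxation_correct(vals, c(muscle = 1, subcutaneous_fat = 1,
                                     reference_tube = 1))
  expect_equal(out1$si_corrected, vals$corrected)
  out2 <- relaxation_correct(vals, c(muscle = 0.8, subcutaneous_fat = 0.75,
                                     reference_tube = 0.95))
  expect_equal(out2$si_corrected[1], 10)
  expect_error(relaxation_correct(vals, c(muscle = 0.8)), "SCF")

  # factors from timing equal the hand-evaluated saturation-decay product
  expect_equal(relaxation_factor_from_timing(100, 0.5, 40, 15),
               (1 - exp(-100 / 40)) * exp(-0.5 / 15), tolerance = 1e-12)
})

test_that("tube calibration is exact on the printed concentration ladder", {
  conc_na <- c(10, 20, 25, 30, 40)
  si <- 0.7 * conc_na            # noiseless, zero intercept
  cal <- calibrate_references(si, conc_na)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  back <- quantify_concentration(si, cal)
  expect_equal(back$conc_mM, conc_na, tolerance = 1e-9)

  conc_k <- c(240, 210, 180, 150, 120)
  cal_k <- calibrate_references(3 + 0.31 * conc_k, conc_k)
  expect_equal(cal_k$slope, 0.31, tolerance = 1e-9)
  expect_equal(cal_k$intercept, 3, tolerance = 1e-9)

  # degenerate cases
  zero <- calibrate_references(rep(0, 5), conc_na)
  expect_false(zero$valid)
  expect_error(quantify_concentration(c(1, 2), zero), "positive")
  expect_error(calibrate_references(c(1, 2), c(10, 10)), "distinct")

  # arithmetic inverse
  cal2 <- calibrate_references(1 + 0.5 * c(10, 40), c(10, 40))
  expect_equal(quantify_concentration(13.6, cal2)$conc_mM, 25.2, tolerance = 1e-9)
})

test_that("quantification is invariant under global image scaling", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  psf <- psf_spec("gaussian", 15)
  img <- synthesize_xnuclei(tr, m$xn, "na", psf = psf)
  q1 <- quantify_xnuclei(img, m$xn, psf)
  img_k <- volume_image(img$data * 3.7, voxel_size = img$voxel_size,
                        affine = img$affine, modality_tag = "na")
  q2 <- quantify_xnuclei(img_k, m$xn, psf)
  expect_equal(attr(q2, "calibration")$slope,
               3.7 * attr(q1, "calibration")$slope, tolerance = 1e-9)
  expect_equal(q2$value, q1$value, tolerance = 1e-9)
})

test_that("noiseless full-chain recovery of phantom concentrations", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  psf <- psf_spec("gaussian", 15)
  for (nuc in c("na", "k")) {
    img <- synthesize_xnuclei(tr, m$xn, nuc, psf = psf)
    q <- quantify_xnuclei(img, m$xn, psf)
    truth_col <- if (nuc == "na") tr$regions$na_mM else tr$regions$k_mM
    fat_c <- if (nuc == "na") 7.9 else 0
    ff <- tr$regions$fat_fraction
    apparent <- (1 - ff) * truth_col + ff * fat_c
    apparent[tr$regions$class == "reference_tube"] <-
      truth_col[tr$regions$class == "reference_tube"]
    mus <- q$class == "muscle"
    truth_app <- apparent[match(q$region, tr$regions$name)]
    expect_lt(max(abs(q$value[mus] - truth_app[mus]) / truth_app[mus]), 0.005)
    expect_equal(attr(q, "calibration")$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("PVC is robust to moderate PSF mismatch", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  img <- synthesize_xnuclei(tr, m$xn, "na", psf = psf_spec("gaussian", 15))
  ref <- quantify_xnuclei(img, m$xn, psf_spec("gaussian", 15))
  for (fw in c(15 * 0.75, 15 * 1.25)) {
    q <- quantify_xnuclei(img, m$xn, psf_spec("gaussian", fw))
    mus <- q$class == "muscle"
    rel_err <- abs(q$value[mus] - ref$value[mus]) / ref$value[mus]
    expect_lt(max(rel_err), 0.15)
  }
})
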