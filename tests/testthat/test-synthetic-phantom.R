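test_that("phantom rasterisation is deterministic, disjoint, and matches analytic areas", {
  tr <- phantom_truth()
  m1 <- build_leg_phantom(tr)
  m2 <- build_leg_phantom(tr)
  expect_identical(m1$h1$label_map$data, m2$h1$label_map$data)
  expect_identical(m1$xn$label_map$data, m2$xn$label_map$data)

  # one integer per voxel makes labels disjoint by construction; all named
  # regions must be non-empty on the 1H grid
  expect_true(all(m1$h1$label_table$n_voxels >= 1))

  # labelled voxel area vs analytic ellipse area pi*a*b, per slice
  geo <- tr$geometry[tr$geometry$name == "SOL", ]
  vox_area <- prod(tr$h1_voxel[1:2])
  n_per_slice <- sum(m1$h1$label_map$data[, , 1] ==
                       m1$h1$label_table$label[m1$h1$label_table$name == "SOL"])
  expect_lt(abs(n_per_slice * vox_area - pi * geo$a * geo$b) / (pi * geo$a * geo$b), 0.05)
})

test_that("overlapping geometry warns and the earlier region keeps the voxels", {
  reg <- phantom_regions("control")[1:2, ]
  geo <- tibble::tibble(name = c("GM", "GL"), cx = c(40, 50), cy = c(40, 40),
                        a = c(15, 15), b = c(15, 15))
  tr <- phantom_truth(regions = reg, geometry = geo,
                      h1_dims = c(32L, 32L, 1L), h1_voxel = c(3, 3, 6),
                      xn_dims = c(8L, 8L, 1L), xn_voxel = c(12, 12, 6))
  w <- capture_warnings(m <- build_leg_phantom(tr))  # one warning per grid
  expect_true(all(grepl("contested", w)) && length(w) >= 1)
  lab <- m$h1$label_map$data
  # contested voxels (inside both ellipses) belong to GM (painted first)
  xyz <- 3 * (which(lab == 1L, arr.ind = TRUE) - 0.5)
  expect_true(any(((xyz[, 1] - 50) / 15)^2 + ((xyz[, 2] - 40) / 15)^2 <= 1))
})

test_that("Dixon synthesis matches the closed-form signal model", {
  tr <- uniform_disc_truth(ff = 0.4, psi = 30, r2star = 40)
  m <- build_leg_phantom(tr)
  te <- default_dixon_tes()
  dx <- synthesize_dixon(tr, m$h1, echo_times = te)
  sel <- which(m$h1$label_map$data == 1L)[1]
  got <- vapply(dx$volumes, function(v) v$data[sel], complex(1))
  expected <- hand_dixon_signal(te, 0.4, 30, 40, default_fat_spectrum())
  expect_equal(got, expected, tolerance = 1e-12)

  # model limit: pure water, on-resonance, no decay -> constant magnitude
  tr0 <- uniform_disc_truth(ff = 0, psi = 0, r2star = 0)
  dx0 <- synthesize_dixon(tr0, build_leg_phantom(tr0)$h1, echo_times = te)
  mag <- vapply(dx0$volumes, function(v) abs(v$data[sel]), numeric(1))
  expect_equal(mag, rep(1, length(te)), tolerance = 1e-12)

  expect_error(synthesize_dixon(tr, m$h1, echo_times = c(1, 1, 2)), "spacing")
})

test_that("MESE synthesis matches mono- and bi-exponential closed forms", {
  te <- default_mese_tes()
  tr <- uniform_disc_truth(ff = 0, t2w = 30)
  m <- build_leg_phantom(tr)
  sel <- which(m$h1$label_map$data == 1L)[1]
  s0 <- vapply(synthesize_mese(tr, m$h1, te)$volumes, function(v) v$data[sel], numeric(1))
  expect_equal(s0, exp(-te / 30), tolerance = 1e-12)
  # at TE = T2w the signal is exp(-1) of the TE=0 extrapolate
  expect_equal(s0[te == 30], exp(-1), tolerance = 1e-12)

  trf <- uniform_disc_truth(ff = 1)
  fp <- trf$fat_t2
  sf <- vapply(synthesize_mese(trf, build_leg_phantom(trf)$h1, te)$volumes,
               function(v) v$data[sel], numeric(1))
  expect_equal(sf, fp[["c1"]] * exp(-te / fp[["t2f1"]]) +
                 fp[["c2"]] * exp(-te / fp[["t2f2"]]), tolerance = 1e-12)

  expect_error(synthesize_mese(tr, m$h1, te[1:4]), "at least 8 echoes")
})

test_that("noise seeding is reproducible and hits the requested SNR", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  ns <- noise_spec("gaussian_complex", snr = 50, reference_region = "SOL", seed = 7)
  d1 <- synthesize_dixon(tr, m$h1, noise = ns)
  d2 <- synthesize_dixon(tr, m$h1, noise = ns)
  expect_identical(d1$volumes[[1]]$data, d2$volumes[[1]]$data)

  # empirical SNR: pool noise-only voxels over echoes (>= 10k draws)
  bg <- m$h1$label_map$data == 0L
  noise_vals <- unlist(lapply(d1$volumes, function(v) {
    c(Re(v$data[bg]), Im(v$data[bg]))
  }))
  expect_gt(length(noise_vals), 10000)
  clean <- synthesize_dixon(tr, m$h1)
  ref <- mean(abs(clean$volumes[[1]]$data[m$h1$label_map$data ==
    m$h1$label_table$label[m$h1$label_table$name == "SOL"]]))
  expect_lt(abs(ref / sd(noise_vals) - 50) / 50, 0.05)
})

test_that("X-nuclei synthesis: delta PSF identity and erf edge profile", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  img <- synthesize_xnuclei(tr, m$xn, "na", psf = psf_spec("delta"))
  fac <- default_relaxation_factors()
  rm <- region_means(img, m$xn)
  tube3 <- rm$value[rm$region == "TUBE3"]
  expect_equal(tube3, 25 * fac[["reference_tube"]], tolerance = 1e-12)
  gm <- rm$value[rm$region == "GM"]
  ff <- tr$regions$fat_fraction[tr$regions$name == "GM"]
  expect_equal(gm, ((1 - ff) * 23 + ff * 7.9) * fac[["muscle"]], tolerance = 1e-12)

  # 1D step blurred by a Gaussian: matches the analytic erf profile
  dims <- c(64L, 5L, 1L); voxel <- c(2, 2, 2)
  step <- array(0, dims); step[1:32, , ] <- 1
  fwhm <- 8
  blurred <- xmuscle:::gaussian_blur3d(step, c(fwhm, 0, 0), voxel)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  x <- (seq_len(64) - 0.5) * 2      # voxel centres, mm
  edge <- 32 * 2                    # step edge position, mm
  # P(step covers) = 1 - Phi((x - edge)/sigma), i.e. half the complementary
  # erf; compare away from the zero-padded array boundary
  analytic <- 1 - pnorm((x - edge) / sigma_mm)
  interior <- 13:52
  expect_equal(blurred[interior, 3, 1], analytic[interior], tolerance = 1e-6)

  expect_error(synthesize_xnuclei(tr, m$xn, "xx"), "arg")
})

test_that("unknown relaxation classes and bad noise models are errors", {
  tr <- phantom_truth()
  m <- build_leg_phantom(tr)
  expect_error(synthesize_xnuclei(tr, m$xn, "na", psf = psf_spec("delta"),
                                  relaxation_factors = c(muscle = 0.8)),
               "relaxation factor")
  expect_error(synthesize_mese(tr, m$h1, noise = noise_spec("gaussian_complex", 50)),
               "rician")
  expect_error(noise_spec("rician_magnitude", snr = -2), "SNR")
})
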