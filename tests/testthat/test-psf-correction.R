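test_that("correction factor matches the Monte-Carlo ball integral and the isotropic closed form", {
  psf <- fx_psf()
  for (d in c(0.3, 0.6, 1.0)) {
    cf <- pbquant:::ball_gaussian_integral(psf, d, 0)
    expect_equal(cf, oracle_mc_cf(psf, d), tolerance = 0.01)
  }
  # isotropic PSF: the ball integral is a chi-squared(3) probability
  iso <- psf_model(0.13, 0.13, 0.13)
  for (d in c(0.2, 0.6, 1.2)) {
    expect_equal(pbquant:::ball_gaussian_integral(iso, d, 0),
                 pchisq((d / 2)^2 / 0.13^2, df = 3), tolerance = 1e-6)
  }
})

test_that("correction curve is monotone, bracketed by its limits, and apparent >= true", {
  curve <- fx_curve_pure()
  expect_true(all(diff(curve$cf) > 0))
  expect_true(all(curve$cf > 0 & curve$cf <= 1))
  # the apparent (blurred) FWHM is monotone in the true diameter, reads
  # above it in the PSF-dominated regime (d below the lateral FWHM), and
  # under-reads in the intermediate regime before converging towards the
  # true diameter for large spheres — the reason lookups are indexed by
  # apparent diameter rather than assuming FWHM == size
  expect_true(all(diff(curve$apparent_diameter) > 0))
  fwhm_lat <- sigma_to_fwhm(0.13)
  psf_dom <- curve$true_diameter <= fwhm_lat
  expect_true(all(curve$apparent_diameter[psf_dom] >=
                  curve$true_diameter[psf_dom]))
  expect_equal(curve$apparent_diameter[nrow(curve)],
               curve$true_diameter[nrow(curve)], tolerance = 0.1)
  psf <- fx_psf()
  big <- 20 * sigma_to_fwhm(psf$sigma_x)
  expect_gte(pbquant:::ball_gaussian_integral(psf, big, 0), 0.999)
  expect_lt(pbquant:::ball_gaussian_integral(psf, 0.02, 0), 0.01)
})

test_that("apparent FWHM of the convolved sphere matches an independent Riemann-sum profile", {
  psf <- fx_psf()
  d <- 0.5
  prof_impl <- vapply(c(0, 0.1, 0.2, 0.3),
                      function(x) pbquant:::ball_gaussian_integral(psf, d, x),
                      numeric(1))
  prof_oracle <- oracle_ball_profile(psf, d, c(0, 0.1, 0.2, 0.3))
  expect_equal(prof_impl, prof_oracle, tolerance = 0.01)
})

test_that("cf_lookup interpolates on apparent diameter, clamps above the grid and rejects below the minimum", {
  curve <- fx_curve_pure()
  i <- 10L
  expect_equal(cf_lookup(curve, curve$apparent_diameter[i]), curve$cf[i],
               tolerance = 1e-12)
  expect_identical(cf_lookup(curve, max(curve$apparent_diameter) + 1), 1.0)
  err <- tryCatch(cf_lookup(curve, 0.2), error = conditionMessage)
  expect_match(err, "minimum analyzable diameter")
  expect_match(err, "0.33") # the threshold appears in the message
})

test_that("minimum analyzable diameter is 1.1 x the lateral FWHM", {
  psf <- psf_model(fwhm_to_sigma(0.30), sigma_z = 0.34)
  expect_equal(min_analyzable_diameter(psf), 0.33, tolerance = 1e-12)
  # a 0.33 um measurement passes, 0.32 um is rejected
  curve <- build_correction_curve(psf, seq(0.1, 2, by = 0.1))
  expect_silent(cf_lookup(curve, 0.33))
  expect_error(cf_lookup(curve, 0.32), "minimum analyzable")
  # linear in sigma; anisotropic case uses the geometric-mean FWHM
  psf2 <- psf_model(2 * fwhm_to_sigma(0.30), sigma_z = 0.34)
  expect_equal(min_analyzable_diameter(psf2), 0.66, tolerance = 1e-12)
  psf3 <- psf_model(fwhm_to_sigma(0.2), fwhm_to_sigma(0.45),
                    sigma_z = 0.34)
  expect_equal(min_analyzable_diameter(psf3), 1.1 * sqrt(0.2 * 0.45),
               tolerance = 1e-12)
})

test_that("PSF is recovered from synthetic beads, with finite-size bias removed by quadrature subtraction", {
  psf <- fx_psf()
  # near-point sources reproduce the PSF sigmas
  tiny <- generate_bead_stack(psf, bead_diameter = 0.02, n_beads = 4,
                              seed = 11)
  est0 <- estimate_psf_from_beads(tiny, 0.02)
  expect_equal(est0$sigma_x, psf$sigma_x, tolerance = 0.02)
  expect_equal(est0$sigma_y, psf$sigma_y, tolerance = 0.02)
  expect_equal(est0$sigma_z, psf$sigma_z, tolerance = 0.02)

  # 0.2 um beads: corrected within 3%; uncorrected biased high by the
  # quadrature-predicted amount
  beads <- generate_bead_stack(psf, bead_diameter = 0.2, n_beads = 5,
                               seed = 12)
  est <- estimate_psf_from_beads(beads, 0.2)
  expect_equal(est$sigma_x, psf$sigma_x, tolerance = 0.03)
  expect_equal(est$sigma_z, psf$sigma_z, tolerance = 0.03)
  raw <- estimate_psf_from_beads(beads, bead_diameter = 1e-6)
  expect_equal(raw$sigma_x, sqrt(psf$sigma_x^2 + (0.2 / 4)^2),
               tolerance = 0.03)
  expect_gt(raw$sigma_x, est$sigma_x)
})

test_that("an empty stack raises a no-beads error", {
  psf <- fx_psf()
  empty <- generate_bead_stack(psf, 0.2, n_beads = 0, seed = 1)
  expect_error(estimate_psf_from_beads(empty, 0.2), "no beads")
})

test_that("measured apparent FWHM of a noiseless P body matches the curve prediction within a voxel", {
  curve <- fx_curve()
  for (d in c(0.5, 0.8)) {
    sim <- generate_cell_stack(single_cell_truth(d, 100), voxel_size = fx_voxel)
    cells <- segment_cells(sim$stack)
    cmask <- array(FALSE, dim = sim$stack$dim)
    cmask[cells[[1]]$mask_idx] <- TRUE
    objs <- detect_pbodies(sim$stack, "GFP", fx_psf(), cell_mask = cmask)
    expect_length(objs, 1L)
    predicted <- approx(curve$true_diameter, curve$apparent_diameter, d)$y
    expect_equal(objs[[1]]$fwhm_xy_um, predicted, tolerance = fx_voxel[1] / predicted)
  }
})

test_that("PSF-corrected peak intensity recovers the true peak within 2% for analyzable diameters", {
  curve <- fx_curve()
  for (d in c(0.4, 0.6, 0.8)) {
    tr <- single_cell_truth(d, 100)
    sim <- generate_cell_stack(tr, voxel_size = fx_voxel)
    img <- sim$stack$channels$GFP
    I_cyto <- 10 + 400 * 0.2
    cf <- cf_lookup(curve, approx(curve$true_diameter,
                                  curve$apparent_diameter, d)$y)
    rec <- correct_pbody_intensity(max(img), I_cyto, cf)
    true_peak <- 10 + 400 * tr$pbodies$c_pbody[1]
    expect_equal(rec, true_peak, tolerance = 0.02)
  }
})

test_that("PSF YAML and correction-curve CSV round-trip through disk", {
  psf <- fx_psf()
  f1 <- tempfile(fileext = ".yaml")
  write_psf(psf, f1)
  psf2 <- read_psf(f1)
  expect_equal(psf2$sigma_x, psf$sigma_x)
  expect_equal(psf2$sigma_z, psf$sigma_z)

  curve <- build_correction_curve(psf, seq(0.2, 1, by = 0.2))
  f2 <- tempfile(fileext = ".csv")
  write_correction_curve(curve, f2)
  curve2 <- read_correction_curve(f2, psf = psf)
  expect_equal(curve2$cf, curve$cf, tolerance = 1e-8)
  expect_equal(cf_lookup(curve2, 0.6), cf_lookup(curve, 0.6),
               tolerance = 1e-6)
})
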