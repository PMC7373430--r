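test_that("a noiseless cell with no P bodies images at gain * C_cyto + offset in its interior", {
  psf <- fx_psf()
  tr <- ground_truth(
    cells = data.frame(cx = 2.5, cy = 2.5, cz = 1.5, dx = 4.2, dy = 4.0,
                       dz = 2.8, c_cyto = 1),
    psf = psf, gain = 100, offset = 7, noise = NOISELESS, seed = 1)
  sim <- generate_cell_stack(tr, voxel_size = fx_voxel)
  img <- sim$stack$channels$GFP
  centre <- round(c(2.5, 2.5, 1.5) / fx_voxel)
  interior <- img[(centre[1] - 5):(centre[1] + 5),
                  (centre[2] - 5):(centre[2] + 5), centre[3]]
  expect_equal(as.numeric(interior), rep(107, length(interior)),
               tolerance = 0.005)
  expect_identical(sim$truth, tr)
})

test_that("the peak of a rendered P body follows the PSF dilution forward model", {
  # max voxel = offset + gain * (C_cyto + (C_p - C_cyto) * CF(d)), with CF
  # from the Monte-Carlo ball-integral oracle
  psf <- fx_psf()
  d <- 0.6
  tr <- single_cell_truth(d, 100, seed = 3)
  sim <- generate_cell_stack(tr, voxel_size = fx_voxel)
  cf_mc <- oracle_mc_cf(psf, d)
  predicted <- 10 + 400 * (0.2 + (20 - 0.2) * cf_mc)
  expect_equal(max(sim$stack$channels$GFP), predicted, tolerance = 0.02)
})

test_that("stack generation is seed-deterministic and noise-only across seeds", {
  noise <- list(photons_per_au = 20, read_sd = 1.5)
  a <- generate_cell_stack(single_cell_truth(0.6, 50, noise = noise,
                                             seed = 5), fx_voxel)
  b <- generate_cell_stack(single_cell_truth(0.6, 50, noise = noise,
                                             seed = 5), fx_voxel)
  expect_identical(a$stack$channels$GFP, b$stack$channels$GFP)
  c2 <- generate_cell_stack(single_cell_truth(0.6, 50, noise = noise,
                                              seed = 6), fx_voxel)
  expect_false(identical(a$stack$channels$GFP, c2$stack$channels$GFP))
  # noiseless renderings are seed-independent
  n1 <- generate_cell_stack(single_cell_truth(0.6, 50, seed = 5), fx_voxel)
  n2 <- generate_cell_stack(single_cell_truth(0.6, 50, seed = 6), fx_voxel)
  expect_identical(n1$stack$channels$GFP, n2$stack$channels$GFP)
})

test_that("invalid geometries are rejected", {
  psf <- fx_psf()
  cells <- data.frame(cx = 2.5, cy = 2.5, cz = 1.5, dx = 4, dy = 4, dz = 3,
                      c_cyto = 0.2)
  expect_error(
    ground_truth(cells,
                 data.frame(x = 6, y = 2.5, z = 1.5, d = 0.5, c_pbody = 5,
                            cell = 1),
                 psf = psf),
    "outside its parent cell")
  expect_error(
    ground_truth(cells,
                 data.frame(x = 2.5, y = 2.5, z = 1.5, d = 0.5,
                            c_pbody = 0.1, cell = 1),
                 psf = psf),
    "c_pbody < c_cyto")
  tr <- ground_truth(cells, psf = psf)
  expect_error(generate_cell_stack(tr, voxel_size = c(0.2, 0.2, 0.2)),
               "lateral voxel")
  expect_error(generate_cell_stack(tr, voxel_size = c(0.05, 0.05, 0.5)),
               "axial voxel")
})

test_that("bead stacks honour n = 0 and refuse impossible packings", {
  psf <- fx_psf()
  empty <- generate_bead_stack(psf, 0.2, n_beads = 0, seed = 1,
                               offset = 10)
  expect_equal(max(abs(empty$channels$beads - 10)), 0)
  expect_error(
    generate_bead_stack(psf, 0.2, n_beads = 500, seed = 1,
                        extent = c(4, 4, 4)),
    "could not place beads")
})

test_that("paired tables reach the requested log-scale correlation", {
  t1 <- generate_paired_table(100, 1, seed = 2)
  expect_equal(pearson_r(log(t1$C_x), log(t1$C_y)), 1, tolerance = 1e-10)
  t2 <- generate_paired_table(10000, 0.65, seed = 3)
  expect_equal(pearson_r(log(t2$C_x), log(t2$C_y)), 0.65, tolerance = 0.031)
  expect_identical(generate_paired_table(50, 0.5, seed = 9),
                   generate_paired_table(50, 0.5, seed = 9))
  # Fisher-z 95% CI coverage at n = 1000
  for (rho in c(0.3, 0.65)) {
    tt <- generate_paired_table(1000, rho, seed = 4)
    r <- pearson_r(log(tt$C_x), log(tt$C_y))
    z <- atanh(r) - atanh(rho)
    expect_lt(abs(z), 1.96 / sqrt(1000 - 3))
  }
})

test_that("standard-curve data round-trips through the OLS fit", {
  pts <- generate_standard_curve_data(400, 10, c(0, 0.5, 1, 5, 20))
  fit <- fit_standard_curve(pts, "A")
  expect_equal(fit$gain, 400, tolerance = 1e-10)
  expect_equal(fit$offset, 10, tolerance = 1e-10)
  # noisy: recovered gain within 2 standard errors
  noisy <- generate_standard_curve_data(400, 10, rep(c(0, 1, 2, 5, 10), 10),
                                        noise_sd = 1, seed = 7)
  nf <- fit_standard_curve(noisy, "A")
  se <- summary(lm(intensity_au ~ concentration_uM,
                   noisy))$coefficients[2, 2]
  expect_lt(abs(nf$gain - 400), 2 * se)
  expect_error(
    fit_standard_curve(generate_standard_curve_data(400, 10, c(2, 2, 2))),
    "distinct concentrations")
})

test_that("stacks survive a TIFF write/read round trip", {
  sim <- generate_cell_stack(single_cell_truth(0.6, 30, seed = 2), fx_voxel)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(sim$stack, path)
  back <- read_stack_tiff(path)
  expect_equal(back$voxel_size, sim$stack$voxel_size)
  expect_equal(back$channels$GFP, sim$stack$channels$GFP, tolerance = 1e-6)
})
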