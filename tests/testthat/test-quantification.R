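test_that("standard-curve fitting is an OLS line with guarded failure modes", {
  fit <- fit_standard_curve(data.frame(concentration_uM = c(0, 1),
                                       intensity_au = c(5, 105)), "A")
  expect_equal(fit$gain, 100, tolerance = 1e-12)
  expect_equal(fit$offset, 5, tolerance = 1e-12)
  expect_error(
    fit_standard_curve(data.frame(concentration_uM = c(0, 1),
                                  intensity_au = c(105, 5))),
    "gain is not positive")
})

test_that("nine-pixel peak measurement averages the max pixel and its one-pixel circle", {
  img <- array(7, dim = c(5, 5, 3))
  expect_equal(measure_pbody_intensity(img, list(max_voxel = c(3L, 3L, 2L))),
               7)
  img2 <- array(50, dim = c(5, 5, 3))
  img2[3, 3, 2] <- 100
  expect_equal(measure_pbody_intensity(img2, list(max_voxel = c(3L, 3L, 2L))),
               (100 + 8 * 50) / 9, tolerance = 1e-12)
  expect_error(measure_pbody_intensity(img2, list(max_voxel = c(1L, 3L, 2L))),
               "edge")
})

test_that("nine-pixel reading of a noiseless P body matches the rendered forward model", {
  sim <- generate_cell_stack(single_cell_truth(0.6, 100, seed = 5), fx_voxel)
  objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
  I9 <- measure_pbody_intensity(sim$stack, objs[[1]])
  curve <- fx_curve()
  cf9 <- approx(curve$true_diameter, curve$cf_ninepixel, 0.6)$y
  expect_equal(I9, 10 + 400 * (0.2 + (20 - 0.2) * cf9), tolerance = 0.02)
})

test_that("cytoplasm ROI measurement is unbiased, deterministic and guarded", {
  img <- array(42, dim = c(60, 60, 5))
  st <- image_stack(img, fx_voxel)
  cellmask <- which(array(TRUE, dim = c(60, 60, 5)))
  obj <- list(max_voxel = c(30L, 30L, 3L), fwhm_xy_um = 0.5,
              voxel_idx = integer(0))
  cell <- list(mask_idx = cellmask)
  for (seed in c(1, 99)) {
    expect_equal(measure_cyto_intensity(st, obj, cell, seed = seed), 42)
  }
  # same seed, same placement on a non-uniform image
  img2 <- img
  withr::with_seed(5, img2[] <- img2 + rnorm(length(img2)))
  st2 <- image_stack(pmax(img2, 0), fx_voxel)
  v1 <- measure_cyto_intensity(st2, obj, cell, seed = 11)
  v2 <- measure_cyto_intensity(st2, obj, cell, seed = 11)
  expect_identical(v1, v2)
  # insufficient cytoplasm: a sliver cell cannot host three ROIs
  tiny <- list(mask_idx = which(slice.index(array(0, c(60, 60, 5)), 1) <= 5))
  expect_error(measure_cyto_intensity(st, obj, tiny, seed = 1),
               "insufficient cytoplasm")
})

test_that("cytoplasm measured in a noiseless synthetic cell equals gain * C_cyto + offset", {
  sim <- generate_cell_stack(single_cell_truth(0.6, 100, seed = 5), fx_voxel)
  cells <- segment_cells(sim$stack)
  objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
  v <- measure_cyto_intensity(sim$stack, objs[[1]], cells[[1]], seed = 2)
  expect_equal(v, 10 + 400 * 0.2, tolerance = 0.01)
})

test_that("PSF correction of the peak follows the incremental-intensity formula", {
  expect_equal(correct_pbody_intensity(60, 10, 0.5), 110)
  expect_equal(correct_pbody_intensity(60, 10, 1), 60)
  expect_equal(correct_pbody_intensity(10, 10, 0.3), 10)
  expect_error(correct_pbody_intensity(60, 10, 0), "cf")
  expect_error(correct_pbody_intensity(60, 10, 1.2), "cf")
  expect_warning(correct_pbody_intensity(5, 10, 0.5), "below cytoplasm")
})

test_that("acquisition-setting mismatch between image and curve is a hard error", {
  sim <- generate_cell_stack(single_cell_truth(0.6, 100, seed = 5), fx_voxel)
  cells <- segment_cells(sim$stack)
  objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
  expect_error(
    quantify_object(sim$stack, objs[[1]], fx_scurve(), fx_curve(),
                    cells[[1]], setting_id = "B"),
    "setting mismatch")
})

test_that("the full noiseless measurement chain recovers the partition coefficient within 5%", {
  q <- recover_measurement(0.6, 100)
  expect_false(is.null(q))
  expect_equal(q$pc, 100, tolerance = 0.05)
  expect_equal(q$C_pbody, 20, tolerance = 0.05)
  expect_equal(q$C_cyto, 0.2, tolerance = 0.02)
  expect_true(q$puncta_flag)
  # omitting the CF correction underestimates the PC
  pc_uncorrected <- ((q$I_pbody_measured - 10) / 400) /
                    ((q$I_cyto - 10) / 400)
  expect_lt(pc_uncorrected / 100, 1)
})

test_that("concentrations and PC are invariant to the camera gain", {
  run_with_gain <- function(gain) {
    tr <- ground_truth(
      cells = data.frame(cx = 2.525, cy = 2.525, cz = 1.5, dx = 4.2,
                         dy = 4.0, dz = 2.8, c_cyto = 0.2),
      pbodies = data.frame(x = 1.825, y = 2.525, z = 1.5, d = 0.6,
                           c_pbody = 20, cell = 1),
      psf = fx_psf(), gain = gain, offset = 10, noise = NOISELESS, seed = 1)
    sim <- generate_cell_stack(tr, voxel_size = fx_voxel)
    cells <- segment_cells(sim$stack)
    objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
    sc <- fit_standard_curve(
      generate_standard_curve_data(gain, 10, c(0, 0.5, 1, 5, 20)), "A")
    quantify_object(sim$stack, objs[[1]], sc, fx_curve(), cells[[1]],
                    seed = 3)
  }
  q1 <- run_with_gain(400)
  q2 <- run_with_gain(800)
  expect_equal(q2$C_pbody, q1$C_pbody, tolerance = 1e-6)
  expect_equal(q2$C_cyto, q1$C_cyto, tolerance = 1e-6)
  expect_equal(q2$pc, q1$pc, tolerance = 1e-6)
})

test_that("recovered PC increases strictly with true PC on noiseless inputs", {
  rec <- vapply(c(5, 30, 130), function(pc) recover_pc(0.6, pc),
                numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("independent recruitment elements multiply: expected fusion PC", {
  expect_equal(synergy_expected_pc(c(2.5, 3.5)), 8.75)
  expect_error(synergy_expected_pc(c(2, -1)))
})
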