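test_that("MaxEntropy and Otsu thresholds equal their exhaustive-search oracles", {
  withr::with_seed(21, {
    imgs <- list(
      bimodal = c(rnorm(4000, 30, 4), rnorm(1000, 120, 10)),
      skewed = rlnorm(5000, 3, 0.6),
      eightbit = sample(0:255, 5000, replace = TRUE,
                        prob = (dnorm(0:255, 60, 25) +
                                dnorm(0:255, 180, 15))))
  })
  for (x in imgs) {
    expect_equal(kapur_maxentropy_threshold(x), oracle_kapur(x),
                 tolerance = 1e-12)
    expect_equal(otsu_threshold(x), oracle_otsu(x), tolerance = 1e-12)
  }
  two <- rep(c(10, 100), each = 50)
  expect_gt(kapur_maxentropy_threshold(two), 10)
  expect_lt(kapur_maxentropy_threshold(two), 100)
  expect_gt(otsu_threshold(two), 10)
  expect_lt(otsu_threshold(two), 100)
  expect_error(kapur_maxentropy_threshold(rep(5, 100)), "constant")
  expect_error(otsu_threshold(rep(5, 100)), "constant")
})

test_that("connected-component labeling respects 26- vs 6-connectivity", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE # diagonal neighbour
  m[4, 4, 4] <- TRUE # far corner
  l26 <- label_components(m, 26L)
  expect_equal(max(l26), 2L)
  expect_equal(l26[1, 1, 1], l26[2, 2, 2])
  l6 <- label_components(m, 6L)
  expect_equal(max(l6), 3L)
})

test_that("detection finds exactly the rendered P body and rejects sub-resolution objects", {
  sim <- generate_cell_stack(single_cell_truth(0.6, 100, seed = 4), fx_voxel)
  objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
  expect_length(objs, 1L)
  expect_lt(max(abs(objs[[1]]$centroid_um - c(1.825, 2.525, 1.5)) /
                fx_voxel), 1)
  # a 0.2 um object has FWHM below the analyzable minimum: empty result
  sub <- generate_cell_stack(single_cell_truth(0.2, 100, seed = 4), fx_voxel)
  expect_length(detect_pbodies(sub$stack, "GFP", fx_psf()), 0L)
})

test_that("a bright marker channel rescues detection of weakly partitioned cargo", {
  # GFP PC ~2 is sub-threshold alone; the mCherry marker defines the mask
  tr <- single_cell_truth(0.6, 2, seed = 8, marker = 30)
  sim <- generate_cell_stack(tr, voxel_size = fx_voxel)
  alone <- detect_pbodies(sim$stack, "GFP", fx_psf())
  with_marker <- detect_pbodies(sim$stack, "GFP", fx_psf(),
                                marker_channel = "mCherry")
  expect_length(with_marker, 1L)
  expect_lt(max(abs(with_marker[[1]]$centroid_um - c(1.825, 2.525, 1.5)) /
                fx_voxel), 1.5)
  # geometry mismatch between channels is an error
  bad <- sim$stack
  bad$channels$mCherry <- bad$channels$mCherry[, , 1:3]
  expect_error(detect_pbodies(bad, "GFP", fx_psf(),
                              marker_channel = "mCherry"), "geometry")
})

test_that("FWHM measurement obeys the Gaussian identity and is symmetric", {
  vs <- c(0.1, 0.1, 0.1)
  n <- 41L
  sigma_vox <- 4
  prof <- 100 * exp(-((1:n) - 21)^2 / (2 * sigma_vox^2))
  img <- array(0, dim = c(n, n, 3))
  for (i in 1:n) for (j in 1:n) {
    img[i, j, 2] <- 100 * exp(-(((i - 21)^2 + (j - 21)^2) /
                                (2 * sigma_vox^2)))
  }
  fw <- measure_fwhm_diameter(img, list(max_voxel = c(21L, 21L, 2L)),
                              baseline = 0, voxel_size = vs)
  expect_equal(fw, 2.3548 * sigma_vox * vs[1], tolerance = 0.01)
  wx <- pbquant:::profile_fwhm(img[, 21, 2], 21L, 0)
  wy <- pbquant:::profile_fwhm(img[21, , 2], 21L, 0)
  expect_equal(wx, wy, tolerance = 1e-12)
  # a profile that never falls to half maximum is not resolvable
  broad <- array(90, dim = c(9, 9, 3))
  broad[5, 5, 2] <- 100
  expect_error(
    measure_fwhm_diameter(broad, list(max_voxel = c(5L, 5L, 2L)),
                          baseline = 0, voxel_size = vs),
    "not resolvable")
})

test_that("FWHM is stable under voxel-grid refinement", {
  d <- 0.6
  tr <- single_cell_truth(d, 100)
  f <- function(vox) {
    sim <- generate_cell_stack(tr, voxel_size = c(vox, vox, 0.2))
    objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
    objs[[1]]$fwhm_xy_um
  }
  expect_equal(f(0.05), f(0.025), tolerance = 0.02)
})

test_that("cell segmentation recovers ellipsoid axes and handles degenerate input", {
  sim <- generate_cell_stack(
    ground_truth(cells = data.frame(cx = 3, cy = 2.6, cz = 1.9, dx = 5,
                                    dy = 4, dz = 3, c_cyto = 0.3),
                 psf = fx_psf(), gain = 400, offset = 10,
                 noise = NOISELESS, seed = 1),
    voxel_size = fx_voxel)
  cells <- segment_cells(sim$stack)
  expect_length(cells, 1L)
  # the Otsu cut sits slightly below mid-amplitude for unequal class
  # weights, shifting each blurred edge outward by up to a voxel
  ax <- cells[[1]]$axes_um
  expect_lt(abs(ax[["x"]] - 5) / fx_voxel[1], 2.5)
  expect_lt(abs(ax[["y"]] - 4) / fx_voxel[2], 2.5)
  expect_lt(abs(ax[["z"]] - 3) / fx_voxel[3], 2.5)
  # a sphere comes out isotropic
  sph <- generate_cell_stack(
    ground_truth(cells = data.frame(cx = 2.2, cy = 2.2, cz = 2.2, dx = 3.4,
                                    dy = 3.4, dz = 3.4, c_cyto = 0.3),
                 psf = fx_psf(), gain = 400, offset = 10,
                 noise = NOISELESS, seed = 1),
    voxel_size = c(0.05, 0.05, 0.1))
  sc <- segment_cells(sph$stack)
  axs <- sc[[1]]$axes_um
  expect_lt(abs(axs[["x"]] - axs[["y"]]), 0.11)
  expect_lt(abs(axs[["x"]] - axs[["z"]]), 0.11)
  # constant image: no cells
  flat <- image_stack(array(5, dim = c(16, 16, 4)), fx_voxel)
  expect_length(segment_cells(flat), 0L)
})

test_that("expression-outlier trimming removes floor(0.1 n) per tail, stably under ties", {
  mkcells <- function(intens) {
    lapply(seq_along(intens), function(i)
      list(id = i, mean_intensity = intens[i]))
  }
  out20 <- filter_expression_outliers(mkcells(c(20:1)))
  expect_length(out20, 16L)
  kept <- vapply(out20, function(c) c$mean_intensity, numeric(1))
  expect_setequal(kept, 3:18)
  # survivors keep input order
  expect_identical(kept, c(18, 17, 16, 15, 14, 13, 12, 11, 10, 9, 8, 7, 6,
                           5, 4, 3))
  expect_length(filter_expression_outliers(mkcells(c(5, 1, 3, 2, 4))), 5L)
  # ties at the cut resolve by stable input order: with ten equal values
  # exactly the first-ranked (earliest) tied cell leaves each tail
  tied <- filter_expression_outliers(mkcells(rep(7, 10)))
  ids <- vapply(tied, function(c) c$id, integer(1))
  expect_identical(ids, 2:9)
})

test_that("detection is complete and clean on well-resolved noiseless objects", {
  # recall 1, false positives 0 for d >= 1.2 x minimum and PC >= 10
  for (d in c(0.45, 0.7)) {
    for (pc in c(10, 50)) {
      sim <- generate_cell_stack(single_cell_truth(d, pc, seed = 2),
                                 fx_voxel)
      objs <- detect_pbodies(sim$stack, "GFP", fx_psf())
      expect_length(objs, 1L)
    }
  }
})
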