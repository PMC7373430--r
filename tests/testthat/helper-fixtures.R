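# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

fx_psf <- function() {
  if (is.null(.fx$psf)) .fx$psf <- psf_model(0.13, sigma_z = 0.34)
  .fx$psf
}

fx_voxel <- c(0.05, 0.05, 0.2)

# detection-model correction curve matching fx_voxel sampling
fx_curve <- function() {
  if (is.null(.fx$curve)) {
    .fx$curve <- build_correction_curve(fx_psf(), seq(0.1, 2, by = 0.05),
                                        voxel_size = fx_voxel)
  }
  .fx$curve
}

# pure optics curve (no pixel integration)
fx_curve_pure <- function() {
  if (is.null(.fx$curve_pure)) {
    .fx$curve_pure <- build_correction_curve(fx_psf(), seq(0.1, 2, by = 0.05))
  }
  .fx$curve_pure
}

fx_scurve <- function() {
  if (is.null(.fx$scurve)) {
    .fx$scurve <- fit_standard_curve(
      generate_standard_curve_data(400, 10, c(0, 0.5, 1, 5, 20)), "A")
  }
  .fx$scurve
}

NOISELESS <- list(photons_per_au = 0, read_sd = 0)

# one ellipsoidal cell with a single P body off-centre
single_cell_truth <- function(d = 0.6, pc = 100, c_cyto = 0.2,
                              noise = NOISELESS, seed = 1L, marker = NULL) {
  pb <- data.frame(x = 1.825, y = 2.525, z = 1.5, d = d,
                   c_pbody = c_cyto * pc, cell = 1)
  if (!is.null(marker)) pb$marker <- marker
  ground_truth(
    cells = data.frame(cx = 2.525, cy = 2.525, cz = 1.5, dx = 4.2, dy = 4.0,
                       dz = 2.8, c_cyto = c_cyto),
    pbodies = pb,
    psf = fx_psf(), gain = 400, offset = 10, noise = noise, seed = seed)
}

# full measurement chain on a single-cell stack; returns the
# partition_measurement or NULL on any failure
recover_measurement <- function(d, pc, noise = NOISELESS, seed = 1L) {
  sim <- generate_cell_stack(single_cell_truth(d, pc, noise = noise,
                                               seed = seed),
                             voxel_size = fx_voxel)
  cells <- segment_cells(sim$stack)
  if (!length(cells)) return(NULL)
  cmask <- array(FALSE, dim = sim$stack$dim)
  cmask[cells[[1]]$mask_idx] <- TRUE
  objs <- detect_pbodies(sim$stack, "GFP", fx_psf(), cell_mask = cmask)
  if (!length(objs)) return(NULL)
  o <- objs[[which.max(vapply(objs, function(x) x$max_intensity,
                              numeric(1)))]]
  q <- try(quantify_object(sim$stack, o, fx_scurve(), fx_curve(),
                           cells[[1]], seed = seed + 1L), silent = TRUE)
  if (inherits(q, "try-error")) NULL else q
}

recover_pc <- function(d, pc, noise = NOISELESS, seed = 1L) {
  q <- recover_measurement(d, pc, noise, seed)
  if (is.null(q)) NA_real_ else q$pc
}
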