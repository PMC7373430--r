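#' Ground truth for a synthetic confocal field of cells
#'
#' Describes a field of ellipsoidal yeast-like cells with spherical
#' condensates (P bodies), the imaging model (PSF, camera gain/offset,
#' noise), and a seed. [generate_cell_stack()] renders it into an image.
#'
#' @param cells Data frame with columns `cx, cy, cz` (centre, µm),
#'   `dx, dy, dz` (axis diameters, µm) and `c_cyto` (cytoplasmic
#'   concentration, µM).
#' @param pbodies Data frame with columns `x, y, z` (centre, µm), `d`
#'   (diameter, µm), `c_pbody` (µM) and `cell` (parent cell row index).
#'   Optionally `marker` (marker-channel amplitude, µM-equivalent) to render
#'   an mCherry marker channel. May have zero rows.
#' @param psf A [psf_model()].
#' @param gain Camera gain, a.u. per µM.
#' @param offset Camera offset, a.u. at zero concentration.
#' @param noise List with `photons_per_au` (Poisson shot-noise scaling;
#'   `0` disables) and `read_sd` (Gaussian read noise, a.u.; `0` disables).
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(cells, pbodies = NULL, psf, gain = 400, offset = 10,
                         noise = list(photons_per_au = 20, read_sd = 1.5),
                         seed = 1L) {
  stopifnot(inherits(psf, "psf_model"))
  cells <- as.data.frame(cells)
  need <- c("cx", "cy", "cz", "dx", "dy", "dz", "c_cyto")
  if (!all(need %in% names(cells))) {
    stop("`cells` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(cells[, c("dx", "dy", "dz")] <= 0)) {
    stop("cell axis diameters must be > 0", call. = FALSE)
  }
  if (any(cells$c_cyto < 0)) stop("c_cyto must be >= 0", call. = FALSE)
  if (is.null(pbodies)) {
    pbodies <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          d = numeric(0), c_pbody = numeric(0),
                          cell = integer(0))
  }
  pbodies <- as.data.frame(pbodies)
  if (nrow(pbodies)) {
    needp <- c("x", "y", "z", "d", "c_pbody", "cell")
    if (!all(needp %in% names(pbodies))) {
      stop("`pbodies` needs columns ", paste(needp, collapse = ", "),
           call. = FALSE)
    }
    if (any(pbodies$d <= 0)) stop("P-body diameters must be > 0",
                                  call. = FALSE)
    for (i in seq_len(nrow(pbodies))) {
      cl <- cells[pbodies$cell[i], ]
      r2 <- ((pbodies$x[i] - cl$cx) / (cl$dx / 2))^2 +
            ((pbodies$y[i] - cl$cy) / (cl$dy / 2))^2 +
            ((pbodies$z[i] - cl$cz) / (cl$dz / 2))^2
      if (!is.finite(r2) || r2 > 1) {
        stop(sprintf("P body %d lies outside its parent cell", i),
             call. = FALSE)
      }
      if (pbodies$c_pbody[i] < cl$c_cyto) {
        stop(sprintf("P body %d has c_pbody < c_cyto of its cell", i),
             call. = FALSE)
      }
    }
  }
  stopifnot_scalar_pos(gain, "gain")
  structure(list(cells = cells, pbodies = pbodies, psf = psf, gain = gain,
                 offset = offset,
                 noise = list(photons_per_au = noise$photons_per_au %||% 0,
                              read_sd = noise$read_sd %||% 0),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Render a ground truth into a synthetic confocal stack
#'
#' The ideal image is the concentration field (cytoplasm value inside each
#' cell, condensate value inside each sphere, zero outside) times the camera
#' gain, convolved with the separable anisotropic Gaussian PSF; the camera
#' offset is then added and shot (Poisson) plus read (Gaussian) noise
#' applied. Spheres are rasterized with analytic sub-voxel coverage
#' (5x oversampling of boundary voxels) so that small P bodies are not
#' aliased; the much larger cell ellipsoids use a half-voxel linear edge
#' ramp instead.
#'
#' @param truth A [ground_truth()].
#' @param voxel_size µm per voxel along x, y, z. Lateral voxels must be at
#'   most half the lateral PSF FWHM (Nyquist for FWHM measurement), the
#'   axial voxel at most half the axial FWHM.
#' @param extent Optional c(x, y, z) stack extent in µm; defaults to the
#'   cell bounding box plus a 0.8 µm margin.
#' @return List with `stack` (an [image_stack()]; channels `GFP` and, if the
#'   truth has marker amplitudes, `mCherry`) and `truth` (unchanged).
#' @examples
#' psf <- psf_model(0.13, sigma_z = 0.34)
#' tr <- ground_truth(
#'   cells = data.frame(cx = 2.5, cy = 2.5, cz = 1.6, dx = 4.2, dy = 4.0,
#'                      dz = 3.0, c_cyto = 0.2),
#'   pbodies = data.frame(x = 2.5, y = 2.5, z = 1.6, d = 0.6,
#'                        c_pbody = 20, cell = 1),
#'   psf = psf, seed = 7)
#' sim <- generate_cell_stack(tr, voxel_size = c(0.05, 0.05, 0.2))
#' sim$stack
#' @export
generate_cell_stack <- function(truth, voxel_size = c(0.05, 0.05, 0.2),
                                extent = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  f <- psf_fwhm(truth$psf)
  lat <- sqrt(f["x"] * f["y"])[[1]]
  if (voxel_size[1] > lat / 2 || voxel_size[2] > lat / 2) {
    stop(sprintf(
      "lateral voxel size must be <= half the lateral PSF FWHM (%.3g um)",
      lat / 2), call. = FALSE)
  }
  if (voxel_size[3] > f["z"] / 2) {
    stop(sprintf("axial voxel size must be <= half the axial PSF FWHM (%.3g um)",
                 f["z"] / 2), call. = FALSE)
  }
  cl <- truth$cells
  if (is.null(extent)) {
    margin <- 0.8
    extent <- c(max(cl$cx + cl$dx / 2) + margin,
                max(cl$cy + cl$dy / 2) + margin,
                max(cl$cz + cl$dz / 2) + margin)
  }
  dims <- pmax(ceiling(extent / voxel_size), 8L)
  # optics blur the scene before the detector integrates it into voxels, so
  # render on a finer internal z grid (the axial step undersamples small
  # spheres) and bin the blurred planes back down
  kz <- min(4L, max(1L, ceiling(voxel_size[3] / (truth$psf$sigma_z / 3))))
  vfine <- c(voxel_size[1], voxel_size[2], voxel_size[3] / kz)
  dfine <- c(dims[1], dims[2], dims[3] * kz)
  xs <- (seq_len(dfine[1]) - 0.5) * vfine[1]
  ys <- (seq_len(dfine[2]) - 0.5) * vfine[2]
  zs <- (seq_len(dfine[3]) - 0.5) * vfine[3]

  render <- function(field) {
    bin_z(gaussian_blur_3d(field, truth$psf, vfine), kz)
  }

  conc <- array(0, dim = dfine)
  for (i in seq_len(nrow(cl))) {
    conc <- conc + cl$c_cyto[i] *
      ellipsoid_coverage(xs, ys, zs, c(cl$cx[i], cl$cy[i], cl$cz[i]),
                         c(cl$dx[i], cl$dy[i], cl$dz[i]) / 2, vfine)
  }
  pb <- truth$pbodies
  for (i in seq_len(nrow(pb))) {
    conc <- add_sphere_coverage(conc, xs, ys, zs,
                                c(pb$x[i], pb$y[i], pb$z[i]), pb$d[i] / 2,
                                pb$c_pbody[i] - cl$c_cyto[pb$cell[i]],
                                vfine)
  }

  ideal <- render(conc * truth$gain)
  channels <- list(GFP = apply_camera_noise(ideal, truth$offset, truth$noise,
                                            truth$seed))

  if (nrow(pb) && "marker" %in% names(pb) && any(pb$marker > 0)) {
    mconc <- array(0, dim = dfine)
    for (i in seq_len(nrow(pb))) {
      mconc <- add_sphere_coverage(mconc, xs, ys, zs,
                                   c(pb$x[i], pb$y[i], pb$z[i]), pb$d[i] / 2,
                                   pb$marker[i], vfine)
    }
    mideal <- render(mconc * truth$gain)
    channels$mCherry <- apply_camera_noise(mideal, truth$offset, truth$noise,
                                           truth$seed + 1L)
  }
  list(stack = image_stack(channels, voxel_size), truth = truth)
}

# average groups of kz consecutive z planes (detector pixel integration)
bin_z <- function(arr, kz) {
  if (kz == 1L) return(arr)
  d <- dim(arr)
  nz <- d[3] %/% kz
  out <- array(0, dim = c(d[1], d[2], nz))
  for (z in seq_len(nz)) {
    sl <- arr[, , ((z - 1L) * kz + 1L):(z * kz), drop = FALSE]
    out[, , z] <- apply(sl, c(1, 2), mean)
  }
  out
}

# fractional ellipsoid coverage with a half-voxel linear edge ramp
ellipsoid_coverage <- function(xs, ys, zs, centre, semi, voxel_size) {
  rx2 <- ((xs - centre[1]) / semi[1])^2
  ry2 <- ((ys - centre[2]) / semi[2])^2
  rz2 <- ((zs - centre[3]) / semi[3])^2
  r <- sqrt(outer(outer(rx2, ry2, "+"), rz2, "+"))
  delta <- 0.5 * sqrt(sum(voxel_size^2)) / exp(mean(log(semi)))
  pmin(1, pmax(0, (1 + delta - r) / (2 * delta)))
}

# add value * coverage for a sphere; boundary voxels oversampled 5x per axis
add_sphere_coverage <- function(arr, xs, ys, zs, centre, R, value, voxel_size,
                                oversample = 5L) {
  hd <- 0.5 * sqrt(sum(voxel_size^2))
  ix <- which(abs(xs - centre[1]) <= R + hd)
  iy <- which(abs(ys - centre[2]) <= R + hd)
  iz <- which(abs(zs - centre[3]) <= R + hd)
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  dx2 <- (xs[ix] - centre[1])^2
  dy2 <- (ys[iy] - centre[2])^2
  dz2 <- (zs[iz] - centre[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  cov <- array(0, dim = dim(dist))
  cov[dist <= R - hd] <- 1
  edge <- which(dist > R - hd & dist < R + hd, arr.ind = TRUE)
  if (nrow(edge)) {
    off <- (seq_len(oversample) - 0.5) / oversample - 0.5
    sub <- as.matrix(expand.grid(off * voxel_size[1], off * voxel_size[2],
                                 off * voxel_size[3]))
    for (k in seq_len(nrow(edge))) {
      cx <- xs[ix[edge[k, 1]]]; cy <- ys[iy[edge[k, 2]]]
      cz <- zs[iz[edge[k, 3]]]
      d2 <- (cx + sub[, 1] - centre[1])^2 + (cy + sub[, 2] - centre[2])^2 +
            (cz + sub[, 3] - centre[3])^2
      cov[edge[k, 1], edge[k, 2], edge[k, 3]] <- mean(d2 <= R^2)
    }
  }
  # explicit dims: single-index slices would otherwise drop to vectors
  sub <- array(arr[ix, iy, iz], dim = dim(cov))
  arr[ix, iy, iz] <- sub + value * cov
  arr
}

# separable Gaussian convolution, zero padding at the borders
gaussian_blur_3d <- function(arr, psf, voxel_size) {
  sig <- c(psf$sigma_x, psf$sigma_y, psf$sigma_z)
  for (ax in 1:3) {
    k <- gaussian_kernel(sig[ax], voxel_size[ax])
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

gaussian_kernel <- function(sigma, pitch) {
  hw <- max(1L, ceiling(4 * sigma / pitch))
  x <- (-hw:hw) * pitch
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve along one axis via banded-matrix multiplication
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1]
  hw <- (length(kernel) - 1L) / 2
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - hw - 1L
    i <- seq_len(n)
    tgt <- i + off
    ok <- tgt >= 1L & tgt <= n
    K[cbind(i[ok], tgt[ok])] <- K[cbind(i[ok], tgt[ok])] + kernel[j]
  }
  m <- K %*% matrix(a, nrow = n)
  a <- array(m, dim = da)
  aperm(a, order(perm))
}

apply_camera_noise <- function(ideal, offset, noise, seed) {
  img <- ideal
  withr::with_seed(seed, {
    ppa <- noise$photons_per_au %||% 0
    if (is.numeric(ppa) && ppa > 0) {
      img <- stats::rpois(length(img), lambda = pmax(img, 0) * ppa) / ppa
      dim(img) <- dim(ideal)
    }
    img <- img + offset
    rs <- noise$read_sd %||% 0
    if (is.numeric(rs) && rs > 0) {
      img <- img + stats::rnorm(length(img), sd = rs)
      dim(img) <- dim(ideal)
    }
  })
  pmax(img, 0)
}

#' Synthetic bead z-stack with a known PSF
#'
#' Renders `n_beads` uniform spheres of the given diameter at random,
#' non-overlapping positions, blurred with the PSF — the input expected by
#' [estimate_psf_from_beads()].
#'
#' @param psf A [psf_model()].
#' @param bead_diameter Bead diameter in µm (0.2 µm microspheres typically).
#' @param n_beads Number of beads (0 gives a background-only stack).
#' @param seed Integer seed.
#' @param extent,voxel_size Stack geometry in µm.
#' @param amplitude Peak-equivalent bead brightness before blurring (a.u.).
#' @param offset,read_sd Camera offset and Gaussian read noise (a.u.).
#' @param min_separation Minimum centre-to-centre distance in µm; default 8x
#'   the lateral PSF FWHM keeps fits independent.
#' @return An [image_stack()] with one channel `beads`.
#' @export
generate_bead_stack <- function(psf, bead_diameter = 0.2, n_beads = 9,
                                seed = 1L,
                                extent = c(12.8, 12.8, 6),
                                voxel_size = c(0.05, 0.05, 0.15),
                                amplitude = 2000, offset = 10, read_sd = 0,
                                min_separation = NULL) {
  stopifnot(inherits(psf, "psf_model"))
  stopifnot_scalar_pos(bead_diameter, "bead_diameter")
  f <- psf_fwhm(psf)
  min_separation <- min_separation %||% (8 * sqrt(f["x"] * f["y"])[[1]])
  dims <- ceiling(extent / voxel_size)
  xs <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  margin <- 5 * c(psf$sigma_x, psf$sigma_y, psf$sigma_z) + bead_diameter

  centres <- matrix(numeric(0), 0, 3)
  if (n_beads > 0) {
    withr::with_seed(seed, {
      tries <- 0L
      while (nrow(centres) < n_beads) {
        tries <- tries + 1L
        if (tries > 200L * n_beads) {
          stop("could not place beads without overlap; reduce n_beads",
               call. = FALSE)
        }
        p <- stats::runif(3, min = margin, max = extent - margin)
        if (nrow(centres) == 0L ||
            min(sqrt(rowSums(sweep(centres, 2, p)^2))) >= min_separation) {
          centres <- rbind(centres, p)
        }
      }
    })
  }

  field <- array(0, dim = dims)
  for (i in seq_len(nrow(centres))) {
    field <- add_sphere_coverage(field, xs, ys, zs, centres[i, ],
                                 bead_diameter / 2, amplitude, voxel_size)
  }
  img <- gaussian_blur_3d(field, psf, voxel_size)
  img <- apply_camera_noise(img, offset,
                            list(photons_per_au = 0, read_sd = read_sd),
                            seed + 1L)
  st <- image_stack(list(beads = img), voxel_size)
  attr(st, "bead_centres") <- centres
  st
}

#' Ground truth for a synthetic FRAP / iFRAP experiment
#'
#' @param k Exchange rate, 1/s.
#' @param frac Fractional recovery (recovery mode) or fractional decay
#'   (decay mode), in `[0, 1]`.
#' @param I0 Normalized intensity at the first post-bleach frame. For decay
#'   mode the first frame defines the normalization, so `I0 = 1`.
#' @param acq_bleach_rate Photobleaching by image acquisition, 1/s,
#'   applied to every fluorescence channel.
#' @param cyto_bleach_factor Ratio of cytoplasm intensity after/before the
#'   bleach pulse, in (0, 1].
#' @param noise_sd Gaussian noise, as a fraction of the pre-bleach signal.
#' @param sample_interval,duration Acquisition cadence in seconds
#'   (5 s for 150 s by default).
#' @param seed Integer seed.
#' @param mode `"recovery"` (FRAP) or `"decay"` (iFRAP).
#' @return An object of class `kinetic_ground_truth`.
#' @export
kinetic_ground_truth <- function(k, frac, I0 = if (mode == "decay") 1 else 0.2,
                                 acq_bleach_rate = 0, cyto_bleach_factor = 1,
                                 noise_sd = 0, sample_interval = 5,
                                 duration = 150, seed = 1L,
                                 mode = c("recovery", "decay")) {
  mode <- match.arg(mode)
  stopifnot(k >= 0, frac >= 0, frac <= 1, sample_interval > 0,
            duration >= 3 * sample_interval,
            cyto_bleach_factor > 0, cyto_bleach_factor <= 1)
  Iinf <- if (mode == "recovery") I0 + frac * (1 - I0) else I0 - frac
  structure(list(k = k, frac = frac, I0 = I0, Iinf = Iinf,
                 acq_bleach_rate = acq_bleach_rate,
                 cyto_bleach_factor = cyto_bleach_factor,
                 noise_sd = noise_sd, sample_interval = sample_interval,
                 duration = duration, seed = as.integer(seed), mode = mode),
            class = "kinetic_ground_truth")
}

#' Simulate a FRAP or iFRAP trace
#'
#' The latent normalized trace is \eqn{I(t) = I_\infty + (I_0-I_\infty)
#' e^{-kt}} on the post-bleach timebase (t = 0 at the first post-bleach
#' frame). Observed channels add a background offset, acquisition
#' photobleaching at `acq_bleach_rate` on the ROI and the unbleached
#' reference, a cytoplasm bleach factor relating the before/after cytoplasm
#' readings, and Gaussian noise. The construction is the exact inverse of
#' [normalize_frap()] / [normalize_ifrap()], so noiseless traces round-trip
#' to the latent curve.
#'
#' @param kt A [kinetic_ground_truth()].
#' @param background,scale,cyto_level Background offset, pre-bleach ROI
#'   signal and cytoplasm signal in a.u.
#' @return A [frap_trace()].
#' @export
generate_frap_trace <- function(kt, background = 50, scale = 1000,
                                cyto_level = 300) {
  stopifnot(inherits(kt, "kinetic_ground_truth"))
  t <- seq(0, kt$duration, by = kt$sample_interval)
  latent <- kt$Iinf + (kt$I0 - kt$Iinf) * exp(-kt$k * t)
  acq <- exp(-kt$acq_bleach_rate * t)
  cbf <- kt$cyto_bleach_factor
  roi <- background + scale * (latent / cbf) * acq
  unbleached <- background + scale * acq
  withr::with_seed(kt$seed, {
    if (kt$noise_sd > 0) {
      roi <- roi + stats::rnorm(length(t), sd = kt$noise_sd * scale)
      unbleached <- unbleached + stats::rnorm(length(t),
                                              sd = kt$noise_sd * scale)
    }
  })
  frap_trace(t = t, I_roi = roi, I_unbleached = unbleached,
             I_background = background,
             I_cyto_before = background + cyto_level,
             I_cyto_after = background + cyto_level * cbf,
             I_prebleach = background + scale,
             mode = kt$mode)
}

#' Synthetic co-partitioning table of two proteins
#'
#' Draws `n` P bodies with bivariate-lognormal concentrations of proteins X
#' and Y whose log-scale Pearson correlation is `rho` — the structure of
#' paired partition measurements of co-resident condensate proteins.
#'
#' @param n Number of P bodies (rows).
#' @param rho Target log-scale Pearson correlation, |rho| <= 1.
#' @param mean_conc Length-2 median concentrations in µM for X and Y.
#' @param sdlog Log-scale standard deviation (common to both proteins).
#' @param seed Integer seed.
#' @return A `paired_partition_table` data frame with columns `pbody_id`,
#'   `cell_id`, `C_x`, `C_y`.
#' @export
generate_paired_table <- function(n, rho, mean_conc = c(10, 10), sdlog = 0.5,
                                  seed = 1L) {
  stopifnot(n >= 3, abs(rho) <= 1, all(mean_conc > 0), sdlog >= 0)
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  })
  out <- data.frame(pbody_id = seq_len(n), cell_id = seq_len(n),
                    C_x = exp(log(mean_conc[1]) + sdlog * z1),
                    C_y = exp(log(mean_conc[2]) + sdlog * z2))
  class(out) <- c("paired_partition_table", "data.frame")
  out
}

#' Synthetic GFP standard-curve measurements
#'
#' Intensity = gain * concentration + offset + Gaussian noise, one row per
#' measurement — the input expected by [fit_standard_curve()].
#'
#' @param gain a.u. per µM. @param offset a.u.
#' @param concentrations µM; at least two distinct values for a usable curve.
#' @param noise_sd Gaussian noise in a.u.
#' @param seed Integer seed.
#' @param setting_id Acquisition-setting label attached to every row.
#' @return Data frame with `concentration_uM`, `intensity_au`, `setting_id`.
#' @export
generate_standard_curve_data <- function(gain, offset, concentrations,
                                         noise_sd = 0, seed = 1L,
                                         setting_id = "A") {
  stopifnot_scalar_pos(gain, "gain")
  intensity <- gain * concentrations + offset
  withr::with_seed(seed, {
    if (noise_sd > 0) {
      intensity <- intensity + stats::rnorm(length(intensity), sd = noise_sd)
    }
  })
  data.frame(concentration_uM = concentrations, intensity_au = intensity,
             setting_id = setting_id)
}
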