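#' PSF dilution-correction curve for small spheres
#'
#' A fluorescent sphere smaller than (or comparable to) the PSF appears
#' dimmer at its centre than it really is, because the PSF spreads its signal
#' into the surroundings. Convolving a unit-intensity ball of diameter d with
#' the normalized PSF gives, at the ball centre, the fraction of true maximum
#' intensity actually observed — the correction factor CF(d). The same
#' convolved profile also yields the *apparent* (blurred) diameter, measured
#' as the FWHM of the x-profile through the centre, which is what a
#' microscopist actually measures.
#'
#' The ball integral of the separable Gaussian is reduced to a 1-D quadrature
#' over slices along x: the cross-section at offset x is a disk of radius
#' \eqn{\sqrt{R^2-x^2}} in (y,z), and the probability mass of a centred
#' bivariate normal inside that disk is itself a closed form when
#' \eqn{\sigma_y=\sigma_z} and a second 1-D quadrature otherwise.
#'
#' @param psf A [psf_model()].
#' @param diameters Ascending grid of true sphere diameters in µm.
#' @param voxel_size Optional voxel size in µm (length 1 = lateral only, 2 =
#'   lateral and axial, or 3 per axis). When given, the curve describes
#'   what the camera records from sampled data: `cf` becomes the exact box
#'   average of the convolved-sphere model over the centre voxel, a
#'   `cf_ninepixel` column is added for the nine-pixel peak-averaging
#'   convention of [measure_pbody_intensity()] (the max pixel plus its
#'   one-pixel circle, which reads slightly below the centre value for
#'   objects near the PSF size), and the apparent diameter uses the
#'   detection PSF (the optics Gaussian widened in quadrature by the voxel
#'   box, \eqn{\sigma_{eff}^2 = \sigma^2 + p^2/12}). Quantification uses
#'   `cf_ninepixel` when present, so the correction undoes exactly what the
#'   measurement convention reads.
#' @return A `correction_curve`: data frame with columns `true_diameter`,
#'   `apparent_diameter`, `cf` (and optionally `cf_ninepixel`), carrying
#'   the PSF as an attribute.
#' @examples
#' psf <- psf_model(0.13, sigma_z = 0.34)
#' curve <- build_correction_curve(psf, seq(0.1, 2, by = 0.1))
#' head(curve)
#' @export
build_correction_curve <- function(psf, diameters = seq(0.05, 2.5, by = 0.05),
                                   voxel_size = NULL) {
  stopifnot(inherits(psf, "psf_model"))
  if (length(diameters) < 2L || any(diameters <= 0) ||
      any(diff(diameters) <= 0)) {
    stop("`diameters` must be an ascending positive grid", call. = FALSE)
  }
  psf_det <- psf
  if (!is.null(voxel_size)) {
    stopifnot(is.numeric(voxel_size), length(voxel_size) %in% 1:3,
              all(voxel_size > 0))
    vs <- if (length(voxel_size) == 1L) c(voxel_size, voxel_size, 0)
          else if (length(voxel_size) == 2L)
            c(voxel_size[1], voxel_size[1], voxel_size[2])
          else voxel_size
    psf_det <- psf_model(sqrt(psf$sigma_x^2 + vs[1]^2 / 12),
                         sqrt(psf$sigma_y^2 + vs[2]^2 / 12),
                         sqrt(psf$sigma_z^2 + vs[3]^2 / 12),
                         provenance = paste0(psf$provenance,
                                             " + pixel integration"))
  }
  # with a voxel size, cf is the exact box average of the pure-optics model
  # over the centre voxel (what the brightest pixel records); the apparent
  # diameter uses the quadrature-widened detection PSF
  cf <- if (is.null(voxel_size)) {
    vapply(diameters, function(d) ball_gaussian_integral(psf, d, 0),
           numeric(1))
  } else {
    vapply(diameters, function(d) boxavg_cf(psf, d, vs), numeric(1))
  }
  app <- vapply(diameters, function(d) apparent_sphere_fwhm(psf_det, d),
                numeric(1))
  out <- data.frame(true_diameter = diameters,
                    apparent_diameter = app,
                    cf = cf)
  if (!is.null(voxel_size)) {
    out$cf_ninepixel <- vapply(diameters, function(d)
      ninepixel_cf(psf, d, vs), numeric(1))
  }
  attr(out, "psf") <- psf
  class(out) <- c("correction_curve", "data.frame")
  out
}

# Value of (unit ball of diameter d) * (PSF) at an arbitrary 3-D offset.
# Slices along x; the (y, z) cross-section is a disk whose offset
# probability mass under the anisotropic bivariate normal is a second 1-D
# quadrature with the z direction integrated analytically.
ball_gaussian_offset <- function(psf, d, cx, cy, cz, n_nodes = 48) {
  R <- d / 2
  gx <- gauss_legendre(n_nodes, -R, R)
  g1 <- gauss_legendre(n_nodes)
  disks <- vapply(gx$x, function(x) {
    rho <- sqrt(max(R^2 - x^2, 0))
    if (rho <= 0) return(0)
    y <- cy + rho * g1$x
    w <- rho * g1$w
    h <- sqrt(pmax(rho^2 - (y - cy)^2, 0))
    sum(w * stats::dnorm(y, sd = psf$sigma_y) *
          (stats::pnorm((cz + h) / psf$sigma_z) -
           stats::pnorm((cz - h) / psf$sigma_z)))
  }, numeric(1))
  sum(gx$w * stats::dnorm(gx$x - cx, sd = psf$sigma_x) * disks)
}

# average of the convolved-sphere profile over a voxel box centred at a
# lateral offset (the value a pixel actually records)
voxel_avg_ball <- function(psf, d, cx, cy, vs, n_box = 3) {
  bx <- gauss_legendre(n_box, -vs[1] / 2, vs[1] / 2)
  by <- gauss_legendre(n_box, -vs[2] / 2, vs[2] / 2)
  bz <- gauss_legendre(n_box, -vs[3] / 2, vs[3] / 2)
  s <- 0
  for (i in seq_len(n_box)) for (j in seq_len(n_box)) {
    for (k in seq_len(n_box)) {
      s <- s + bx$w[i] * by$w[j] * bz$w[k] *
        ball_gaussian_offset(psf, d, cx + bx$x[i], cy + by$x[j], bz$x[k])
    }
  }
  s / prod(vs)
}

# centre-voxel CF as read by the camera: box average at zero offset
boxavg_cf <- function(psf, d, vs) {
  voxel_avg_ball(psf, d, 0, 0, vs)
}

# mean of the pixel-averaged profile over the max pixel and its one-pixel
# circle: centre + 4 at offset p + 4 at the diagonal offset (p, p)
ninepixel_cf <- function(psf, d, vs) {
  p <- sqrt(vs[1] * vs[2])
  (voxel_avg_ball(psf, d, 0, 0, vs) +
     4 * voxel_avg_ball(psf, d, p, 0, vs) +
     4 * voxel_avg_ball(psf, d, p, p, vs)) / 9
}

# Value at lateral offset x0 (µm) of (unit ball of diameter d) * (PSF).
# Slices along x: integrand gx(x - x0) * P[(Y,Z) in disk radius sqrt(R^2-x^2)].
ball_gaussian_integral <- function(psf, d, x0 = 0, n_nodes = 96) {
  R <- d / 2
  g <- gauss_legendre(n_nodes, -R, R)
  rho <- sqrt(pmax(R^2 - g$x^2, 0))
  disk <- disk_normal_prob(rho, psf$sigma_y, psf$sigma_z, n_nodes)
  sum(g$w * stats::dnorm(g$x - x0, sd = psf$sigma_x) * disk)
}

# P(Y^2 + Z^2 <= rho^2) for independent centred normals; vectorized over rho.
# Closed form for sy == sz; otherwise 1-D Gauss-Legendre in y with the z
# direction integrated analytically via pnorm.
disk_normal_prob <- function(rho, sy, sz, n_nodes = 96) {
  if (isTRUE(all.equal(sy, sz))) {
    return(1 - exp(-rho^2 / (2 * sy^2)))
  }
  g <- gauss_legendre(n_nodes) # on [-1, 1], scaled per rho
  vapply(rho, function(r) {
    if (r <= 0) return(0)
    y <- r * g$x
    w <- r * g$w
    h <- sqrt(pmax(r^2 - y^2, 0))
    sum(w * stats::dnorm(y, sd = sy) * (2 * stats::pnorm(h / sz) - 1))
  }, numeric(1))
}

# FWHM of the x-profile through the centre of the convolved sphere
apparent_sphere_fwhm <- function(psf, d) {
  half <- ball_gaussian_integral(psf, d, 0) / 2
  f <- function(x) ball_gaussian_integral(psf, d, x) - half
  # profile decays to 0; bracket the half crossing beyond the ball edge
  upper <- d / 2 + 6 * psf$sigma_x
  while (f(upper) > 0) upper <- upper * 1.5
  x_half <- stats::uniroot(f, c(0, upper), tol = 1e-8)$root
  2 * x_half
}

#' @export
print.correction_curve <- function(x, ...) {
  psf <- attr(x, "psf")
  cat(sprintf("Correction curve: %d diameters in [%.3g, %.3g] um\n",
              nrow(x), min(x$true_diameter), max(x$true_diameter)))
  if (!is.null(psf)) {
    cat(sprintf("  PSF sigma (x,y,z) = (%.3g, %.3g, %.3g) um\n",
                psf$sigma_x, psf$sigma_y, psf$sigma_z))
  }
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Look up the correction factor for a measured diameter
#'
#' The pipeline only ever observes *blurred* diameters, so the lookup is
#' indexed by the apparent diameter column of the curve: linear interpolation
#' of CF against apparent diameter, clamped to 1 above the grid. Diameters
#' below the minimum analyzable diameter (1.1 × lateral PSF FWHM) are
#' rejected — their FWHM is dominated by the PSF and carries no reliable
#' size information.
#'
#' @param curve A [build_correction_curve()] result.
#' @param measured_diameter Measured FWHM diameter in µm.
#' @param psf A [psf_model()]; defaults to the one stored in `curve`.
#' @param convention `"centre"` (CF at the sphere centre) or
#'   `"nine_pixel"` (CF of the nine-pixel peak average; requires a curve
#'   built with `pixel_size`).
#' @return CF in (0, 1].
#' @export
cf_lookup <- function(curve, measured_diameter, psf = attr(curve, "psf"),
                      convention = c("centre", "nine_pixel")) {
  stopifnot(inherits(curve, "correction_curve"))
  stopifnot_scalar_pos(measured_diameter, "measured_diameter")
  convention <- match.arg(convention)
  col <- if (convention == "nine_pixel") {
    if (is.null(curve$cf_ninepixel)) {
      stop("curve has no cf_ninepixel column; rebuild with voxel_size",
           call. = FALSE)
    }
    curve$cf_ninepixel
  } else {
    curve$cf
  }
  if (!is.null(psf)) {
    dmin <- min_analyzable_diameter(psf)
    if (measured_diameter < dmin) {
      stop(sprintf(
        "measured diameter %.3g um is below the minimum analyzable diameter %.3g um (1.1 x lateral PSF FWHM)",
        measured_diameter, dmin), call. = FALSE)
    }
  }
  if (measured_diameter >= max(curve$apparent_diameter)) return(1.0)
  if (measured_diameter <= min(curve$apparent_diameter)) {
    return(col[1])
  }
  stats::approx(curve$apparent_diameter, col,
                xout = measured_diameter)$y
}

#' Invert the blur: true diameter from a measured (apparent) FWHM
#'
#' Linear interpolation of true against apparent diameter on the curve grid;
#' above the grid the blur is negligible and the measured value is returned
#' unchanged.
#'
#' @inheritParams cf_lookup
#' @return Estimated true diameter in µm.
#' @export
true_diameter_from_apparent <- function(curve, measured_diameter) {
  stopifnot(inherits(curve, "correction_curve"))
  stopifnot_scalar_pos(measured_diameter, "measured_diameter")
  if (measured_diameter >= max(curve$apparent_diameter)) {
    return(measured_diameter)
  }
  if (measured_diameter <= min(curve$apparent_diameter)) {
    return(curve$true_diameter[1])
  }
  stats::approx(curve$apparent_diameter, curve$true_diameter,
                xout = measured_diameter)$y
}

#' Read / write a correction curve as CSV
#'
#' @param curve A `correction_curve`. @param path File path.
#' @return `read_correction_curve` returns a `correction_curve` (without the
#'   PSF attribute unless supplied); `write_correction_curve` returns `path`
#'   invisibly.
#' @param psf Optional [psf_model()] to attach on read.
#' @export
write_correction_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correction_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correction_curve
#' @export
read_correction_curve <- function(path, psf = NULL) {
  x <- utils::read.csv(path)
  stopifnot(all(c("true_diameter", "apparent_diameter", "cf") %in% names(x)))
  attr(x, "psf") <- psf
  class(x) <- c("correction_curve", "data.frame")
  x
}
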