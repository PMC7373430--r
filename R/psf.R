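#' Anisotropic Gaussian point-spread-function model
#'
#' Confocal PSFs are well approximated by a separable anisotropic Gaussian
#' whose lateral (x-y) width is set by the objective NA and whose axial (z)
#' width is set by the pinhole. All widths are standard deviations in
#' micrometres; full widths at half maximum follow as
#' \eqn{\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma}.
#'
#' @param sigma_x,sigma_y,sigma_z Gaussian standard deviations in µm.
#'   `sigma_y` defaults to `sigma_x` (lateral isotropy).
#' @param provenance Free-text note on where the numbers came from
#'   (a bead-stack file id, or `"configured"`).
#' @return An object of class `psf_model`.
#' @examples
#' psf <- psf_model(sigma_x = 0.13, sigma_z = 0.34)
#' psf_fwhm(psf)
#' @export
psf_model <- function(sigma_x, sigma_y = sigma_x, sigma_z,
                      provenance = "configured") {
  stopifnot_scalar_pos(sigma_x, "sigma_x")
  stopifnot_scalar_pos(sigma_y, "sigma_y")
  stopifnot_scalar_pos(sigma_z, "sigma_z")
  structure(
    list(sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
         provenance = as.character(provenance)),
    class = "psf_model"
  )
}

#' @export
print.psf_model <- function(x, ...) {
  f <- psf_fwhm(x)
  cat(sprintf(
    "Gaussian PSF: sigma (x,y,z) = (%.4g, %.4g, %.4g) um | FWHM = (%.4g, %.4g, %.4g) um\n",
    x$sigma_x, x$sigma_y, x$sigma_z, f[1], f[2], f[3]))
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Full widths at half maximum of a PSF
#'
#' @param psf A [psf_model()].
#' @return Named numeric vector `c(x=, y=, z=)` in µm.
#' @export
psf_fwhm <- function(psf) {
  stopifnot(inherits(psf, "psf_model"))
  c(x = sigma_to_fwhm(psf$sigma_x),
    y = sigma_to_fwhm(psf$sigma_y),
    z = sigma_to_fwhm(psf$sigma_z))
}

#' Smallest object diameter whose FWHM can be trusted
#'
#' Objects must be 1.1 times larger than the lateral PSF FWHM for their full
#' width at half maximum to be an accurate size estimate; smaller objects are
#' excluded from quantification. For anisotropic lateral PSFs the geometric
#' mean of the x and y FWHM is used.
#'
#' @param psf A [psf_model()].
#' @return Minimum analyzable diameter in µm.
#' @examples
#' min_analyzable_diameter(psf_model(fwhm_to_sigma(0.30), sigma_z = 0.34))
#' @export
min_analyzable_diameter <- function(psf) {
  f <- psf_fwhm(psf)
  1.1 * sqrt(f["x"] * f["y"])[[1]]
}

#' Convert between Gaussian sigma and FWHM
#'
#' @param sigma,fwhm Width in any unit.
#' @return The corresponding FWHM or sigma.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' Estimate the PSF from a bead z-stack
#'
#' Sub-resolution fluorescent beads imaged with the acquisition settings of
#' the experiment provide an empirical PSF. Each isolated bead is fit with a
#' separable 3-D Gaussian plus constant background; the finite bead size is
#' removed by quadrature subtraction of the sphere's Gaussian-equivalent
#' standard deviation (d/4), and the median over beads is returned.
#'
#' Beads closer than three apparent lateral FWHM to another bead are
#' excluded as overlapping.
#'
#' @param bead_stack An [image_stack()] containing one channel of beads.
#' @param bead_diameter Physical bead diameter in µm (e.g. 0.2).
#' @param channel Channel name; defaults to the first channel.
#' @param min_snr Peaks below `background + min_snr * mad` are ignored.
#' @return A [psf_model()] with provenance `"beads"`.
#' @export
estimate_psf_from_beads <- function(bead_stack, bead_diameter,
                                    channel = NULL, min_snr = 10) {
  stopifnot(inherits(bead_stack, "image_stack"))
  stopifnot_scalar_pos(bead_diameter, "bead_diameter")
  channel <- channel %||% names(bead_stack$channels)[1]
  img <- bead_stack$channels[[channel]]
  vs <- bead_stack$voxel_size
  bg <- stats::median(img)
  noise <- stats::mad(img)
  thr <- bg + min_snr * max(noise, 1e-12)

  peaks <- find_local_maxima_3d(img, thr)
  if (nrow(peaks) == 0L) stop("no beads found above background", call. = FALSE)

  # rough apparent lateral FWHM to define the exclusion radius
  rough_sigma <- sqrt(fwhm_to_sigma(sigma_to_fwhm(bead_diameter / 4))^2)
  # exclusion uses distances in µm between peak positions
  pos <- cbind(peaks[, 1] * vs[1], peaks[, 2] * vs[2], peaks[, 3] * vs[3])
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 1L) {
    dmat <- as.matrix(stats::dist(pos))
    diag(dmat) <- Inf
    # apparent FWHM is unknown before fitting; use a conservative estimate
    # from the brightest bead's profile half-width
    est_fwhm <- apparent_fwhm_estimate(img, peaks[1, ], vs, bg)
    keep <- apply(dmat, 1, min) >= 3 * est_fwhm
  }
  if (!any(keep)) stop("all beads overlap (nearer than 3 apparent FWHM)",
                       call. = FALSE)
  peaks <- peaks[keep, , drop = FALSE]

  fits <- apply(peaks, 1, function(p) fit_bead_gaussian(img, p, vs, bg))
  fits <- fits[, colSums(is.na(fits)) == 0, drop = FALSE]
  if (ncol(fits) == 0L) stop("no beads could be fit", call. = FALSE)

  sig_app <- apply(fits, 1, stats::median)
  # quadrature subtraction of the sphere's equivalent Gaussian sd (d/4)
  s_bead <- bead_diameter / 4
  sig <- sqrt(pmax(sig_app^2 - s_bead^2, 1e-12))
  psf_model(sig[1], sig[2], sig[3], provenance = "beads")
}

# crude apparent FWHM from the x-profile through one peak (voxels -> µm)
apparent_fwhm_estimate <- function(img, peak, vs, bg) {
  prof <- img[, peak[2], peak[3]] - bg
  pk <- prof[peak[1]]
  above <- which(prof > pk / 2)
  max(diff(range(above)) + 1, 2) * vs[1]
}

# local maxima strictly above thr (6-neighbourhood comparison is enough
# for blurred spots)
find_local_maxima_3d <- function(img, thr) {
  d <- dim(img)
  idx <- which(img > thr)
  if (length(idx) == 0L) return(matrix(integer(0), 0, 3))
  co <- arrayInd(idx, d)
  inside <- co[, 1] > 1 & co[, 1] < d[1] &
            co[, 2] > 1 & co[, 2] < d[2] &
            co[, 3] > 1 & co[, 3] < d[3]
  co <- co[inside, , drop = FALSE]
  if (nrow(co) == 0L) return(matrix(integer(0), 0, 3))
  v <- img[co]
  ismax <- v >= img[co + cbind(rep(1L, nrow(co)), 0L, 0L)] &
           v >= img[co - cbind(rep(1L, nrow(co)), 0L, 0L)] &
           v >= img[co + cbind(0L, rep(1L, nrow(co)), 0L)] &
           v >= img[co - cbind(0L, rep(1L, nrow(co)), 0L)] &
           v >= img[co + cbind(0L, 0L, rep(1L, nrow(co)))] &
           v >= img[co - cbind(0L, 0L, rep(1L, nrow(co)))]
  co <- co[ismax, , drop = FALSE]
  if (nrow(co) == 0L) return(co)
  # deduplicate plateaus: keep one peak per 3-voxel neighbourhood
  o <- order(img[co], decreasing = TRUE)
  co <- co[o, , drop = FALSE]
  sel <- logical(nrow(co))
  for (i in seq_len(nrow(co))) {
    if (i == 1L || all(rowSums(abs(sweep(co[which(sel), , drop = FALSE],
                                         2, co[i, ]))) > 3)) {
      sel[i] <- TRUE
    }
  }
  co[sel, , drop = FALSE]
}

# separable 3-D Gaussian fit around one peak; returns c(sx, sy, sz) in µm
fit_bead_gaussian <- function(img, peak, vs, bg) {
  d <- dim(img)
  # cutout half-widths in voxels, ~5 expected sigma
  hw <- pmax(3L, ceiling(0.8 / vs))
  lo <- pmax(peak - hw, 1L)
  hi <- pmin(peak + hw, d)
  cut <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  xs <- (lo[1]:hi[1]) * vs[1]
  ys <- (lo[2]:hi[2]) * vs[2]
  zs <- (lo[3]:hi[3]) * vs[3]
  grid <- expand.grid(x = xs, y = ys, z = zs)
  val <- as.vector(cut)
  # moment-based initial values
  w <- pmax(val - bg, 0)
  if (sum(w) <= 0) return(c(NA_real_, NA_real_, NA_real_))
  mx <- sum(w * grid$x) / sum(w); sx <- sqrt(sum(w * (grid$x - mx)^2) / sum(w))
  my <- sum(w * grid$y) / sum(w); sy <- sqrt(sum(w * (grid$y - my)^2) / sum(w))
  mz <- sum(w * grid$z) / sum(w); sz <- sqrt(sum(w * (grid$z - mz)^2) / sum(w))
  st <- list(A = max(val) - bg, B = bg, mx = mx, my = my, mz = mz,
             sx = max(sx, vs[1] / 2), sy = max(sy, vs[2] / 2),
             sz = max(sz, vs[3] / 2))
  fit <- try(minpack.lm::nlsLM(
    val ~ B + A * exp(-((x - mx)^2 / (2 * sx^2) + (y - my)^2 / (2 * sy^2) +
                        (z - mz)^2 / (2 * sz^2))),
    data = cbind(grid, val = val), start = st,
    lower = c(A = 0, B = -Inf, mx = -Inf, my = -Inf, mz = -Inf,
              sx = 1e-4, sy = 1e-4, sz = 1e-4),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(c(NA_real_, NA_real_, NA_real_))
  cf <- stats::coef(fit)
  c(cf[["sx"]], cf[["sy"]], cf[["sz"]])
}

#' Read / write a PSF model as YAML
#'
#' @param psf A [psf_model()]. @param path File path.
#' @return `read_psf` returns a [psf_model()]; `write_psf` returns `path`
#'   invisibly.
#' @export
write_psf <- function(psf, path) {
  stopifnot(inherits(psf, "psf_model"))
  yaml::write_yaml(unclass(psf), path)
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  x <- yaml::read_yaml(path)
  psf_model(x$sigma_x, x$sigma_y, x$sigma_z,
            provenance = x$provenance %||% "configured")
}
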