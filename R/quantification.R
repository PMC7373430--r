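#' Fit a GFP standard curve
#'
#' Ordinary least squares of intensity on concentration for purified GFP
#' solutions imaged with the same acquisition settings as the cells. The
#' fitted gain (a.u. per µM) and offset (a.u.) convert intensities to
#' absolute concentrations; curves are tagged with an acquisition-setting id
#' and may only be applied to images acquired with the same settings.
#'
#' @param points Data frame with columns `concentration_uM` and
#'   `intensity_au` (the output of [generate_standard_curve_data()]), or a
#'   two-column matrix.
#' @param setting_id Acquisition-setting label.
#' @return A `standard_curve`: list with `gain`, `offset`, `setting_id`,
#'   `r_squared`, `n`.
#' @examples
#' fit_standard_curve(data.frame(concentration_uM = c(0, 1),
#'                               intensity_au = c(5, 105)), "A")
#' @export
fit_standard_curve <- function(points, setting_id = "A") {
  points <- as.data.frame(points)
  if (!all(c("concentration_uM", "intensity_au") %in% names(points))) {
    names(points)[1:2] <- c("concentration_uM", "intensity_au")
  }
  if (length(unique(points$concentration_uM)) < 2L) {
    stop("need at least 2 distinct concentrations to fit a standard curve",
         call. = FALSE)
  }
  fit <- stats::lm(intensity_au ~ concentration_uM, data = points)
  gain <- unname(stats::coef(fit)[2])
  offset <- unname(stats::coef(fit)[1])
  if (!is.finite(gain) || gain <= 0) {
    stop("fitted gain is not positive; check the standard-curve data",
         call. = FALSE)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared) # noiseless fits are exact
  structure(list(gain = gain, offset = offset,
                 setting_id = as.character(setting_id),
                 r_squared = r2,
                 n = nrow(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve [%s]: gain = %.6g a.u./uM, offset = %.6g a.u. (R2 = %.4f, n = %d)\n",
    x$setting_id, x$gain, x$offset, x$r_squared, x$n))
  invisible(x)
}

#' Measured P-body intensity: 9-pixel average at the peak
#'
#' In the z-plane of the object's maximum voxel, the maximum pixel and its
#' 8 neighbours on a one-pixel circle are averaged.
#'
#' @param stack An [image_stack()] or bare 3-D array.
#' @param object A `detected_object` (anything with `max_voxel`).
#' @param channel Channel name.
#' @return Intensity in a.u.
#' @export
measure_pbody_intensity <- function(stack, object, channel = "GFP") {
  img <- if (inherits(stack, "image_stack")) stack$channels[[channel]] else stack
  mv <- object$max_voxel
  d <- dim(img)
  if (mv[1] <= 1L || mv[1] >= d[1] || mv[2] <= 1L || mv[2] >= d[2]) {
    stop("object maximum is adjacent to the image edge", call. = FALSE)
  }
  mean(img[(mv[1] - 1L):(mv[1] + 1L), (mv[2] - 1L):(mv[2] + 1L), mv[3]])
}

#' Cytoplasm intensity from three random ROIs
#'
#' Three circular ROIs of the object's diameter are placed uniformly at
#' random (seeded) in the cytoplasm of the object's cell, in the z-plane of
#' the object's maximum voxel. The cytoplasm is the cell mask eroded by two
#' pixels, minus all P-body masks dilated by two pixels; ROIs may not
#' overlap each other. The mean of the three ROI means is returned.
#'
#' @param stack An [image_stack()].
#' @param object A `detected_object`.
#' @param cell A `cell_record` (or list with `mask_idx`).
#' @param pbody_idx Linear voxel indices of all P bodies in the cell
#'   (defaults to the object's own mask).
#' @param seed Integer seed; same seed, same placement.
#' @param channel Channel name.
#' @param n_rois Number of ROIs (3).
#' @return Intensity in a.u.
#' @export
measure_cyto_intensity <- function(stack, object, cell, pbody_idx = NULL,
                                   seed = 1L, channel = "GFP", n_rois = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  img <- stack$channels[[channel]]
  vs <- stack$voxel_size
  d <- dim(img)
  z <- object$max_voxel[3]
  pbody_idx <- pbody_idx %||% object$voxel_idx

  # 2-D allowed region in the measurement plane
  plane_cell <- matrix(FALSE, d[1], d[2])
  co <- arrayInd(cell$mask_idx, d)
  inz <- co[, 3] == z
  plane_cell[co[inz, 1:2, drop = FALSE]] <- TRUE
  plane_pb <- matrix(FALSE, d[1], d[2])
  if (length(pbody_idx)) {
    cop <- arrayInd(pbody_idx, d)
    inzp <- cop[, 3] == z
    if (any(inzp)) plane_pb[cop[inzp, 1:2, drop = FALSE]] <- TRUE
  }
  allowed <- erode2d(plane_cell, 2L) & !dilate2d(plane_pb, 2L)

  r_vox <- (object$fwhm_xy_um / 2) / vs[1]
  disk <- disk_offsets(r_vox)
  cand <- which(allowed, arr.ind = TRUE)
  if (nrow(cand) < n_rois) {
    stop("insufficient cytoplasm area to place ROIs", call. = FALSE)
  }
  centres <- matrix(numeric(0), 0, 2)
  withr::with_seed(seed, {
    tries <- 0L
    while (nrow(centres) < n_rois) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop("insufficient cytoplasm area to place ROIs", call. = FALSE)
      }
      p <- cand[sample.int(nrow(cand), 1L), ]
      px <- p[1] + disk[, 1]; py <- p[2] + disk[, 2]
      if (any(px < 1L | px > d[1] | py < 1L | py > d[2])) next
      if (!all(allowed[cbind(px, py)])) next
      if (nrow(centres) &&
          min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) <=
            2 * r_vox) next
      centres <- rbind(centres, p)
    }
  })
  roi_means <- apply(centres, 1, function(p) {
    mean(img[cbind(p[1] + disk[, 1], p[2] + disk[, 2], z)])
  })
  mean(roi_means)
}

disk_offsets <- function(r_vox) {
  r <- max(1L, ceiling(r_vox))
  g <- expand.grid(x = -r:r, y = -r:r)
  g <- g[g$x^2 + g$y^2 <= max(r_vox, 1)^2, ]
  as.matrix(g)
}

erode2d <- function(m, k) {
  for (i in seq_len(k)) {
    s <- m
    s[-1, ] <- s[-1, ] & m[-nrow(m), ]
    s[-nrow(m), ] <- s[-nrow(m), ] & m[-1, ]
    s[, -1] <- s[, -1] & m[, -ncol(m)]
    s[, -ncol(m)] <- s[, -ncol(m)] & m[, -1]
    s[1, ] <- FALSE; s[nrow(m), ] <- FALSE
    s[, 1] <- FALSE; s[, ncol(m)] <- FALSE
    m <- s
  }
  m
}

dilate2d <- function(m, k) {
  for (i in seq_len(k)) {
    s <- m
    s[-1, ] <- s[-1, ] | m[-nrow(m), ]
    s[-nrow(m), ] <- s[-nrow(m), ] | m[-1, ]
    s[, -1] <- s[, -1] | m[, -ncol(m)]
    s[, -ncol(m)] <- s[, -ncol(m)] | m[, -1]
    m <- s
  }
  m
}

#' PSF-corrected P-body peak intensity
#'
#' Only the increment of the P body over the cytoplasm is diluted by the
#' PSF (the cytoplasmic contribution is homogeneous), so the true peak
#' intensity is \eqn{(I_{measured} - I_{cyto}) / CF + I_{cyto}}.
#'
#' @param I_measured 9-pixel P-body intensity, a.u.
#' @param I_cyto Cytoplasm intensity, a.u.
#' @param cf Correction factor in (0, 1] from [cf_lookup()].
#' @return Corrected intensity in a.u. If `I_measured < I_cyto` the value is
#'   returned (below `I_cyto`) with a warning, not clamped.
#' @examples
#' correct_pbody_intensity(60, 10, 0.5) # 110
#' @export
correct_pbody_intensity <- function(I_measured, I_cyto, cf) {
  if (!is.numeric(cf) || length(cf) != 1L || !is.finite(cf) ||
      cf <= 0 || cf > 1) {
    stop("cf must be in (0, 1]", call. = FALSE)
  }
  if (I_measured < I_cyto) {
    warning("measured P-body intensity below cytoplasm; corrected value is below I_cyto")
  }
  (I_measured - I_cyto) / cf + I_cyto
}

#' Quantify one P body: concentrations and partition coefficient
#'
#' Composes the measurement chain: 9-pixel peak intensity, three-ROI
#' cytoplasm intensity, CF lookup from the measured FWHM diameter, PSF
#' correction, then conversion to absolute concentrations through the
#' standard curve (C = (I - offset) / gain) and the partition coefficient
#' PC = C_pbody / C_cyto.
#'
#' @param stack An [image_stack()].
#' @param object A `detected_object` from [detect_pbodies()].
#' @param curve A [fit_standard_curve()] result.
#' @param correction A [build_correction_curve()] result.
#' @param cell The object's `cell_record`.
#' @param pbody_idx Linear indices of all P-body voxels in the cell.
#' @param seed Seed for cytoplasm ROI placement.
#' @param channel Measurement channel.
#' @param setting_id Acquisition-setting id of the image; must match the
#'   standard curve.
#' @return A `partition_measurement`: list with `I_pbody_measured`,
#'   `I_cyto`, `cf`, `I_pbody`, `C_pbody`, `C_cyto`, `pc`, `diameter`,
#'   `puncta_flag` (PC > 2).
#' @export
quantify_object <- function(stack, object, curve, correction, cell,
                            pbody_idx = NULL, seed = 1L, channel = "GFP",
                            setting_id = curve$setting_id) {
  stopifnot(inherits(curve, "standard_curve"),
            inherits(correction, "correction_curve"))
  if (!identical(setting_id, curve$setting_id)) {
    stop(sprintf(
      "acquisition setting mismatch: image '%s' vs standard curve '%s'",
      setting_id, curve$setting_id), call. = FALSE)
  }
  I_meas <- measure_pbody_intensity(stack, object, channel)
  I_cyto <- measure_cyto_intensity(stack, object, cell, pbody_idx, seed,
                                   channel)
  # correct what the nine-pixel convention actually reads when the curve
  # carries that column; otherwise the centre-value CF
  cf <- cf_lookup(correction, object$fwhm_xy_um,
                  convention = if (!is.null(correction$cf_ninepixel))
                    "nine_pixel" else "centre")
  I_pbody <- correct_pbody_intensity(I_meas, I_cyto, cf)
  C_pbody <- (I_pbody - curve$offset) / curve$gain
  C_cyto <- (I_cyto - curve$offset) / curve$gain
  if (C_cyto <= 0) {
    stop("cytoplasm below calibration offset: C_cyto <= 0", call. = FALSE)
  }
  structure(list(
    object_label = object$label,
    I_pbody_measured = I_meas,
    I_cyto = I_cyto,
    cf = cf,
    I_pbody = I_pbody,
    C_pbody = C_pbody,
    C_cyto = C_cyto,
    pc = C_pbody / C_cyto,
    diameter = object$fwhm_xy_um,
    puncta_flag = (C_pbody / C_cyto) > 2),
    class = "partition_measurement")
}

#' @export
print.partition_measurement <- function(x, ...) {
  cat(sprintf(
    "P body: d = %.3g um, CF = %.3f | C_pbody = %.3g uM, C_cyto = %.3g uM, PC = %.3g\n",
    x$diameter, x$cf, x$C_pbody, x$C_cyto, x$pc))
  invisible(x)
}

#' Expected partition coefficient of a fusion under independent recruitment
#'
#' If two recruitment elements contribute independently, their partition
#' free energies add, so the expected PC of the fusion is the product of the
#' individual PCs. A measured fusion PC above this product indicates
#' synergy between the elements.
#'
#' @param pc_elements Numeric vector of element partition coefficients.
#' @return Product of the element PCs.
#' @examples
#' synergy_expected_pc(c(2.5, 3.5)) # 8.75
#' @export
synergy_expected_pc <- function(pc_elements) {
  stopifnot(is.numeric(pc_elements), all(pc_elements > 0))
  prod(pc_elements)
}
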