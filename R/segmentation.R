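#' Kapur maximum-entropy threshold
#'
#' Histogram-entropy threshold of Kapur, Sahoo and Wong — the "MaxEntropy"
#' algorithm of Fiji, used to identify condensates against the cytoplasm.
#' The intensity range is binned into 256 uniform bins and the bin edge
#' maximizing the sum of background and foreground Shannon entropies is
#' returned. Deterministic; ties resolve to the lowest threshold.
#'
#' @param image Numeric array or vector of intensities.
#' @param n_bins Number of histogram bins (256, the Fiji convention).
#' @return Threshold in intensity units (a.u.).
#' @export
kapur_maxentropy_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) stop("image is constant; no threshold exists",
                           call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  obj <- entropy_objective(p)
  t_idx <- which.max(obj)
  edges[t_idx + 1L]
}

# Kapur objective for splitting after bin t (t = 1..n_bins-1)
entropy_objective <- function(p) {
  n <- length(p)
  plogp <- p * log(pmax(p, 1e-300))
  plogp[p == 0] <- 0
  P1 <- cumsum(p)[-n]
  H1 <- cumsum(plogp)[-n]
  Htot <- sum(plogp)
  P2 <- 1 - P1
  Hb <- log(pmax(P1, 1e-300)) - H1 / pmax(P1, 1e-300)
  Hf <- log(pmax(P2, 1e-300)) - (Htot - H1) / pmax(P2, 1e-300)
  obj <- Hb + Hf
  obj[P1 <= 0 | P2 <= 0] <- -Inf
  obj
}

#' Otsu threshold (256-bin)
#'
#' Between-class variance maximizer on a 256-bin histogram over the
#' intensity range, the Fiji convention; used to find cell boundaries from
#' the cytoplasmic GFP signal.
#'
#' @inheritParams kapur_maxentropy_threshold
#' @return Threshold in intensity units (a.u.).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) stop("image is constant; no threshold exists",
                           call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  w1 <- cumsum(p)[-n_bins]
  mu1 <- cumsum(p * mids)[-n_bins]
  mu <- sum(p * mids)
  w2 <- 1 - w1
  ok <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[ok] <- (mu * w1[ok] - mu1[ok])^2 / (w1[ok] * w2[ok])
  edges[which.max(bcv) + 1L]
}

#' Label connected components in a 3-D mask
#'
#' Breadth-first flood fill with 26-connectivity (or 6).
#'
#' @param mask Logical 3-D array.
#' @param connectivity 26 or 6.
#' @return Integer array of the same dim; 0 = background, 1..k component ids
#'   in first-voxel order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  d <- dim(mask)
  # pad with a FALSE shell so neighbour arithmetic never wraps
  dp <- d + 2L
  pm <- array(FALSE, dim = dp)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offs <- neighbour_offsets_lin(dp, connectivity)
  plabels <- integer(prod(dp))
  pmv <- as.logical(pm)
  todo <- which(pmv)
  lab <- 0L
  for (s in todo) {
    if (plabels[s] > 0L) next
    lab <- lab + 1L
    frontier <- s
    plabels[s] <- lab
    while (length(frontier)) {
      cand <- rep(frontier, each = length(offs)) + offs
      cand <- cand[pmv[cand] & plabels[cand] == 0L]
      if (length(cand)) {
        cand <- unique(cand)
        plabels[cand] <- lab
      }
      frontier <- cand
    }
  }
  dim(plabels) <- dp
  labels <- plabels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  array(labels, dim = d)
}

neighbour_offsets_lin <- function(d, connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.integer(g$dx + g$dy * d[1] + g$dz * d[1] * d[2])
}

#' Detect P bodies in a stack
#'
#' Thresholds the marker channel when provided (MaxEntropy; the mask is then
#' transferred to the measurement channel), otherwise the measurement
#' channel itself. Connected components (26-connectivity) become candidate
#' objects; each object's maximum voxel in the measurement channel anchors
#' an FWHM diameter measurement, and objects whose lateral FWHM is at or
#' below the minimum analyzable diameter (1.1 x lateral PSF FWHM) are
#' discarded.
#'
#' @param stack An [image_stack()].
#' @param channel Measurement channel name (default `"GFP"`).
#' @param psf A [psf_model()].
#' @param marker_channel Optional marker channel name used for the mask.
#' @param cell_mask Optional logical array (same dims) restricting the
#'   local-cytoplasm baseline estimate to in-cell voxels; without it the
#'   baseline is the median of a local box excluding the condensate halo.
#' @return List of `detected_object`s: each has `label`, `centroid_um`,
#'   `max_voxel` (index triplet), `max_intensity`, `fwhm_xy_um`,
#'   `voxel_idx` (linear indices of the mask), `baseline`.
#' @export
detect_pbodies <- function(stack, channel = "GFP", psf,
                           marker_channel = NULL, cell_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(psf, "psf_model"))
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("channel not found: ", channel, call. = FALSE)
  thr_src <- if (!is.null(marker_channel)) {
    m <- stack$channels[[marker_channel]]
    if (is.null(m)) stop("marker channel not found: ", marker_channel,
                         call. = FALSE)
    if (!identical(dim(m), dim(img))) {
      stop("marker channel geometry differs from measurement channel",
           call. = FALSE)
    }
    m
  } else {
    img
  }
  thr <- kapur_maxentropy_threshold(thr_src)
  mask <- thr_src > thr
  labels <- label_components(mask, 26L)
  k <- max(labels)
  if (k == 0L) return(list())
  vs <- stack$voxel_size
  dmin <- min_analyzable_diameter(psf)
  out <- list()
  size_channel <- if (!is.null(marker_channel)) marker_channel else channel
  for (lb in seq_len(k)) {
    idx <- which(labels == lb)
    vmax <- idx[which.max(img[idx])]
    mv <- arrayInd(vmax, dim(img))[1, ]
    # the size (FWHM) is measured on the channel that defines the P body:
    # the marker when present, the measurement channel otherwise
    smax <- idx[which.max(thr_src[idx])]
    smv <- arrayInd(smax, dim(img))[1, ]
    sbase <- local_baseline(thr_src, smv, mask, vs, cell_mask = cell_mask)
    fw <- try(measure_fwhm_diameter(stack, list(max_voxel = smv),
                                    channel = size_channel, baseline = sbase),
              silent = TRUE)
    if (inherits(fw, "try-error") || !is.finite(fw) || fw <= dmin) next
    baseline <- if (identical(size_channel, channel)) sbase else
      local_baseline(img, mv, mask, vs, cell_mask = cell_mask)
    co <- arrayInd(idx, dim(img))
    out[[length(out) + 1L]] <- structure(list(
      label = lb,
      centroid_um = c(mean(co[, 1]) * vs[1], mean(co[, 2]) * vs[2],
                      mean(co[, 3]) * vs[3]) -
                    0.5 * vs,
      max_voxel = mv,
      max_intensity = img[vmax],
      fwhm_xy_um = fw,
      voxel_idx = idx,
      baseline = baseline), class = "detected_object")
  }
  out
}

# median intensity in a local box around the object, excluding the
# thresholded (condensate) mask and a halo radius around the peak where
# the PSF tail still contributes: a local cytoplasm estimate
local_baseline <- function(img, max_voxel, exclude_mask, vs,
                           halfwidth_um = 1.2, halo_um = 0.5,
                           cell_mask = NULL) {
  d <- dim(img)
  hw <- pmax(2L, ceiling(halfwidth_um / vs))
  lo <- pmax(max_voxel - hw, 1L)
  hi <- pmin(max_voxel + hw, d)
  box <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  bm <- exclude_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  keep <- !bm
  if (!is.null(cell_mask)) {
    keep <- keep & cell_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  }
  co <- arrayInd(seq_along(box), dim(box))
  dist2 <- ((co[, 1] + lo[1] - 1L - max_voxel[1]) * vs[1])^2 +
           ((co[, 2] + lo[2] - 1L - max_voxel[2]) * vs[2])^2 +
           ((co[, 3] + lo[3] - 1L - max_voxel[3]) * vs[3])^2
  vals <- box[keep & dist2 > halo_um^2]
  if (!length(vals)) vals <- box[keep]
  if (!length(vals)) vals <- as.numeric(box)
  if (!is.null(cell_mask) && length(vals) > 50L &&
      stats::sd(vals) > .Machine$double.eps) {
    # in-cell values are the cytoplasm plateau plus a minority of darker
    # cell-edge (blurred boundary) voxels: the density mode is the plateau
    dens <- stats::density(vals, n = 256)
    dens$x[which.max(dens$y)]
  } else {
    stats::median(vals)
  }
}

#' Measure an object's FWHM diameter
#'
#' Full width at half of (peak - baseline) measured by linear interpolation
#' on the x and y line profiles through the object's maximum voxel, in its
#' z-plane; the mean of the two directions is returned. The baseline is the
#' local cytoplasm intensity.
#'
#' @param stack An [image_stack()] (or a plain 3-D array plus `voxel_size`).
#' @param object A `detected_object`, or any list with `max_voxel`.
#' @param channel Channel name.
#' @param baseline Local cytoplasm intensity (a.u.). Defaults to the
#'   object's stored baseline if present.
#' @param voxel_size Required if `stack` is a bare array.
#' @return FWHM diameter in µm.
#' @export
measure_fwhm_diameter <- function(stack, object, channel = "GFP",
                                  baseline = NULL, voxel_size = NULL) {
  if (inherits(stack, "image_stack")) {
    img <- stack$channels[[channel]]
    vs <- stack$voxel_size
  } else {
    img <- stack
    vs <- voxel_size
    if (is.null(vs)) stop("voxel_size required with a bare array",
                          call. = FALSE)
  }
  mv <- object$max_voxel
  baseline <- baseline %||% object$baseline
  if (is.null(baseline)) stop("baseline (local cytoplasm) required",
                              call. = FALSE)
  peak <- img[mv[1], mv[2], mv[3]]
  if (peak <= baseline) {
    stop("object maximum is not above the cytoplasm baseline", call. = FALSE)
  }
  wx <- profile_fwhm(img[, mv[2], mv[3]], mv[1], baseline) * vs[1]
  wy <- profile_fwhm(img[mv[1], , mv[3]], mv[2], baseline) * vs[2]
  mean(c(wx, wy))
}

# width (in voxel units) at half of (peak - baseline) around position p0
profile_fwhm <- function(prof, p0, baseline) {
  peak <- prof[p0]
  half <- baseline + (peak - baseline) / 2
  right <- NA_real_
  for (i in p0:(length(prof) - 1L)) {
    if (prof[i + 1L] <= half) {
      right <- i + (prof[i] - half) / (prof[i] - prof[i + 1L])
      break
    }
  }
  left <- NA_real_
  for (i in p0:2L) {
    if (prof[i - 1L] <= half) {
      left <- i - (prof[i] - half) / (prof[i] - prof[i - 1L])
      break
    }
  }
  if (!is.finite(right) || !is.finite(left)) {
    stop("object not resolvable: profile never falls to half maximum",
         call. = FALSE)
  }
  right - left
}

#' Segment cells from the cytoplasmic signal
#'
#' Otsu threshold on the chosen channel, hole filling (condensate-free
#' regions such as vacuoles stay inside the cell), 26-connected components,
#' then per-cell axis diameters measured as the extents of the mask along
#' x, y and z through the component centroid.
#'
#' Bright condensate voxels are rare but intense, and would dominate the
#' 256-bin histogram and push the Otsu threshold above the cytoplasm level.
#' When a sparse bright tail is present (less than `suppress_fraction` of
#' voxels above the MaxEntropy threshold), those voxels are excluded from
#' the histogram before running Otsu, which then separates background from
#' cytoplasm at mid-amplitude — where the blurred cell edge sits.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param min_volume_um3 Components smaller than this are dropped (debris).
#' @param suppress_fraction Condensate suppression kicks in when the
#'   MaxEntropy-foreground fraction is below this value.
#' @return List of `cell_record`s: `id`, `mask_idx` (linear indices),
#'   `axes_um` (named x, y, z diameters), `mean_intensity`, `centroid_vox`.
#' @export
segment_cells <- function(stack, channel = "GFP", min_volume_um3 = 2,
                          suppress_fraction = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  img <- stack$channels[[channel]]
  if (is.null(img)) stop("channel not found: ", channel, call. = FALSE)
  vs <- stack$voxel_size
  if (diff(range(img)) <= 0) return(list())
  histo <- as.numeric(img)
  n0 <- length(histo)
  for (i in 1:6) {
    t1 <- try(kapur_maxentropy_threshold(histo), silent = TRUE)
    if (inherits(t1, "try-error")) break
    fa <- sum(histo > t1) / n0
    if (fa == 0) break
    if (fa < suppress_fraction) {
      histo <- histo[histo <= t1]
      next
    }
    # MaxEntropy split background|cell; look for a sparse condensate tail
    # within the upper class
    t2 <- try(kapur_maxentropy_threshold(histo[histo > t1]), silent = TRUE)
    if (inherits(t2, "try-error")) break
    fa2 <- sum(histo > t2) / n0
    if (fa2 > 0 && fa2 < suppress_fraction) {
      histo <- histo[histo <= t2]
      next
    }
    break
  }
  thr <- otsu_threshold(histo)
  mask <- img > thr
  if (!any(mask)) return(list())
  mask <- fill_holes_3d(mask)
  labels <- label_components(mask, 26L)
  vvol <- prod(vs)
  out <- list()
  for (lb in seq_len(max(labels))) {
    idx <- which(labels == lb)
    if (length(idx) * vvol < min_volume_um3) next
    co <- arrayInd(idx, dim(img))
    cen <- round(colMeans(co))
    ax <- c(
      x = sum(co[, 2] == cen[2] & co[, 3] == cen[3]) * vs[1],
      y = sum(co[, 1] == cen[1] & co[, 3] == cen[3]) * vs[2],
      z = sum(co[, 1] == cen[1] & co[, 2] == cen[2]) * vs[3])
    out[[length(out) + 1L]] <- structure(list(
      id = length(out) + 1L,
      mask_idx = idx,
      axes_um = ax,
      mean_intensity = mean(img[idx]),
      centroid_vox = cen), class = "cell_record")
  }
  out
}

# fill interior holes: background components not touching the border
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  inv <- !mask
  labels <- label_components(inv, 6L)
  if (max(labels) == 0L) return(mask)
  border_labels <- unique(c(labels[1, , ], labels[d[1], , ],
                            labels[, 1, ], labels[, d[2], ],
                            labels[, , 1], labels[, , d[3]]))
  border_labels <- setdiff(border_labels, 0L)
  hole <- inv & !(labels %in% border_labels)
  dim(hole) <- d
  mask | hole
}

#' Drop low- and high-expression cells
#'
#' Cells are ranked by mean GFP intensity; the lowest 10% and highest 10%
#' (floor(0.1 n) each) are removed to exclude expression outliers. Input
#' order of the survivors is preserved; ties at the cut are broken by stable
#' input order.
#'
#' @param cells List of `cell_record`s (or any list with `mean_intensity`).
#' @param trim Fraction trimmed from each tail (default 0.10).
#' @return The filtered list.
#' @export
filter_expression_outliers <- function(cells, trim = 0.10) {
  n <- length(cells)
  if (n == 0L) stop("no cells to filter", call. = FALSE)
  k <- floor(trim * n)
  if (k == 0L) return(cells)
  mi <- vapply(cells, function(c) c$mean_intensity, numeric(1))
  o <- order(mi) # ties: stable, first-come-first-ranked
  drop <- c(o[seq_len(k)], o[(n - k + 1L):n])
  cells[setdiff(seq_len(n), drop)]
}
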