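#' Calibrated multi-channel voxel grid
#'
#' Container for a 3-D confocal stack: a named list of 3-D arrays (one per
#' channel, dimensions x, y, z) plus the voxel size in µm per axis.
#'
#' @param channels Named list of 3-D numeric arrays with identical dims.
#' @param voxel_size Numeric length-3, µm per voxel along x, y, z.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  if (is.array(channels)) channels <- list(GFP = channels)
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  d <- dim(channels[[1]])
  if (length(d) != 3L) stop("channels must be 3-D arrays", call. = FALSE)
  for (ch in channels) {
    if (!identical(dim(ch), d)) {
      stop("all channels must share the same dimensions", call. = FALSE)
    }
    if (any(!is.finite(ch)) || any(ch < 0)) {
      stop("intensities must be finite and >= 0", call. = FALSE)
    }
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive numbers (um)", call. = FALSE)
  }
  structure(list(channels = channels, voxel_size = voxel_size,
                 dim = d),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...).
#' Voxel size and channel names are stored in the TIFF description tag.
#' Intensities are stored as 32-bit float.
#'
#' @param stack An [image_stack()]. @param path File path.
#' @return `read_stack_tiff` returns an [image_stack()];
#'   `write_stack_tiff` returns `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  # the tiff float writer stores values in [0, 1]; rescale per channel and
  # record the scale in the sidecar
  scales <- vapply(stack$channels, function(ch) max(ch, 1), numeric(1))
  pages <- list()
  for (ci in seq_along(stack$channels)) {
    ch <- stack$channels[[ci]] / scales[ci]
    for (z in seq_len(dim(ch)[3])) {
      # tiff expects row-major (y, x) matrices
      pages[[length(pages) + 1L]] <- t(ch[, , z])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  # calibration travels in a sidecar so reads are lossless
  yaml::write_yaml(list(voxel_size = stack$voxel_size,
                        channels = names(stack$channels),
                        scales = unname(scales),
                        nz = stack$dim[3]),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param voxel_size,channel_names Calibration to use when the sidecar
#'   metadata file is absent.
#' @export
read_stack_tiff <- function(path, voxel_size = NULL, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.yaml")
  scales <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    voxel_size <- voxel_size %||% as.numeric(meta$voxel_size)
    channel_names <- channel_names %||% meta$channels
    scales <- as.numeric(meta$scales)
    nz <- meta$nz
  } else {
    if (is.null(voxel_size)) {
      stop("no sidecar metadata: supply voxel_size", call. = FALSE)
    }
    channel_names <- channel_names %||% "GFP"
    nz <- length(pages) / length(channel_names)
  }
  nch <- length(channel_names)
  if (is.null(scales) || !length(scales)) scales <- rep(1, nch)
  stopifnot(length(pages) == nch * nz)
  channels <- list()
  for (c_i in seq_len(nch)) {
    planes <- pages[((c_i - 1L) * nz + 1L):(c_i * nz)]
    arr <- array(0, dim = c(ncol(planes[[1]]), nrow(planes[[1]]), nz))
    for (z in seq_len(nz)) arr[, , z] <- t(planes[[z]])
    channels[[channel_names[c_i]]] <- arr * scales[c_i]
  }
  image_stack(channels, voxel_size)
}
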