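#' End-to-end condensate inventory on a set of stacks
#'
#' Orchestrates the full measurement chain on one or more stacks imaged
#' with a common acquisition setting: cell segmentation, expression-outlier
#' trimming, P-body detection, per-object quantification (PSF-corrected
#' concentrations and partition coefficients), per-cell molecule-count
#' bookkeeping, and a study-level summary (mean PC and C_pbody with SEM,
#' sequestered fraction, HC/LC label).
#'
#' By default one P body per cell — the brightest passing the size filter —
#' enters the summary; `all_pbodies = TRUE` quantifies every detection.
#'
#' @param stacks A single [image_stack()] / [generate_cell_stack()] result,
#'   or a list of them.
#' @param psf A [psf_model()], or a bead [image_stack()] from which to
#'   estimate one (then `bead_diameter` is required).
#' @param standard_curve A [fit_standard_curve()] result.
#' @param correction Optional [build_correction_curve()]; built from the
#'   PSF when omitted.
#' @param seed Integer seed (cytoplasm ROI placement).
#' @param channel,marker_channel Measurement and optional marker channel.
#' @param cyto_fraction Cytoplasm fraction of cell volume.
#' @param all_pbodies Quantify every P body instead of one per cell.
#' @param trim Expression-outlier trim fraction per tail.
#' @param bead_diameter Bead diameter (µm) when `psf` is a bead stack.
#' @param out_dir Optional directory for CSV artifacts
#'   (objects.csv, cells.csv, summary.csv, manifest.yaml).
#' @return List with `objects` (per-object data frame), `cells` (per-cell
#'   data frame), `summary` (one-row data frame), `manifest`.
#' @export
run_inventory <- function(stacks, psf, standard_curve, correction = NULL,
                          seed = 1L, channel = "GFP", marker_channel = NULL,
                          cyto_fraction = CYTOPLASM_FRACTION,
                          all_pbodies = FALSE, trim = 0.10,
                          bead_diameter = NULL, out_dir = NULL) {
  if (inherits(stacks, "image_stack") ||
      (is.list(stacks) && !is.null(stacks$stack))) {
    stacks <- list(stacks)
  }
  stacks <- lapply(stacks, function(s) if (inherits(s, "image_stack")) s
                   else s$stack)
  if (inherits(psf, "image_stack")) {
    if (is.null(bead_diameter)) {
      stop("bead_diameter required to estimate the PSF from a bead stack",
           call. = FALSE)
    }
    psf <- estimate_psf_from_beads(psf, bead_diameter)
  }
  stopifnot(inherits(psf, "psf_model"),
            inherits(standard_curve, "standard_curve"))
  correction <- correction %||%
    build_correction_curve(psf, voxel_size = stacks[[1]]$voxel_size)

  # segment every stack, then trim expression outliers cohort-wide
  seg <- list()
  for (si in seq_along(stacks)) {
    for (cl in segment_cells(stacks[[si]], channel)) {
      seg[[length(seg) + 1L]] <- list(stack = si, cell = cl,
                                      mean_intensity = cl$mean_intensity)
    }
  }
  if (length(seg)) seg <- filter_expression_outliers(seg, trim)

  obj_rows <- list()
  cell_rows <- list()
  cell_counter <- 0L
  for (si in seq_along(stacks)) {
    st <- stacks[[si]]
    cells <- lapply(Filter(function(s) s$stack == si, seg),
                    function(s) s$cell)
    if (!length(cells)) next
    d <- st$dim
    cmask <- array(FALSE, dim = d)
    cmask[unlist(lapply(cells, function(c) c$mask_idx))] <- TRUE
    objects <- detect_pbodies(st, channel, psf, marker_channel,
                              cell_mask = cmask)
    all_pb_idx <- unlist(lapply(objects, function(o) o$voxel_idx))
    for (cl in cells) {
      cell_counter <- cell_counter + 1L
      cl_set <- logical(prod(d))
      cl_set[cl$mask_idx] <- TRUE
      mine <- Filter(function(o) {
        cl_set[o$voxel_idx[which.max(st$channels[[channel]][o$voxel_idx])]]
      }, objects)
      if (length(mine) && !all_pbodies) {
        bright <- which.max(vapply(mine, function(o) o$max_intensity,
                                   numeric(1)))
        mine <- mine[bright]
      }
      meas <- list()
      for (o in mine) {
        q <- try(quantify_object(st, o, standard_curve, correction, cl,
                                 pbody_idx = all_pb_idx,
                                 seed = seed + cell_counter,
                                 channel = channel), silent = TRUE)
        if (inherits(q, "try-error")) next
        meas[[length(meas) + 1L]] <- q
        obj_rows[[length(obj_rows) + 1L]] <- data.frame(
          stack = si, cell = cell_counter, object = o$label,
          diameter_um = q$diameter, cf = q$cf,
          I_pbody_measured = q$I_pbody_measured, I_cyto = q$I_cyto,
          I_pbody = q$I_pbody, C_pbody_uM = q$C_pbody,
          C_cyto_uM = q$C_cyto, pc = q$pc, puncta = q$puncta_flag)
      }
      if (length(meas)) {
        dtrue <- vapply(meas, function(q)
          true_diameter_from_apparent(correction, q$diameter), numeric(1))
        sq <- sequestration_result(
          cl$axes_um, dtrue,
          vapply(meas, function(q) q$C_pbody, numeric(1)),
          stats::median(vapply(meas, function(q) q$C_cyto, numeric(1))),
          cyto_fraction)
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          stack = si, cell = cell_counter,
          V_cell_um3 = sq$V_cell, N_cyto = round(sq$N_cyto),
          N_pbody = round(sq$N_pbody), f_p = sq$f_p,
          avg_conc_uM = sq$avg_cell_conc)
      }
    }
  }
  objects_df <- if (length(obj_rows)) do.call(rbind, obj_rows) else
    data.frame()
  cells_df <- if (length(cell_rows)) do.call(rbind, cell_rows) else
    data.frame()

  summary_df <- if (nrow(objects_df)) {
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    mpc <- mean(objects_df$pc)
    mcp <- mean(objects_df$C_pbody_uM)
    data.frame(
      n_objects = nrow(objects_df),
      mean_pc = mpc, sem_pc = sem(objects_df$pc),
      mean_C_pbody_uM = mcp, sem_C_pbody_uM = sem(objects_df$C_pbody_uM),
      mean_C_cyto_uM = mean(objects_df$C_cyto_uM),
      mean_f_p = if (nrow(cells_df)) mean(cells_df$f_p) else NA_real_,
      class = classify_hc_lc(mpc, mcp))
  } else {
    data.frame()
  }

  manifest <- list(
    package = "pbquant",
    version = as.character(utils::packageVersion("pbquant")),
    seed = seed,
    n_stacks = length(stacks),
    channel = channel,
    marker_channel = marker_channel,
    cyto_fraction = cyto_fraction,
    all_pbodies = all_pbodies,
    trim = trim,
    psf = unclass(psf),
    standard_curve = unclass(standard_curve)[c("gain", "offset",
                                               "setting_id")],
    thresholds = list(min_diameter_factor = 1.1, puncta_pc = 2,
                      hc_pc = 30, hc_conc_uM = 5))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(objects_df, file.path(out_dir, "objects.csv"),
                     row.names = FALSE)
    utils::write.csv(cells_df, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(objects = objects_df, cells = cells_df, summary = summary_df,
       manifest = manifest)
}
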