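#' Ellipsoidal cell volume
#'
#' Yeast cells are treated as ellipsoids with axis diameters x, y, z:
#' \eqn{V = \frac{4}{3}\pi \frac{x}{2}\frac{y}{2}\frac{z}{2}}.
#'
#' @param x,y,z Axis diameters in µm.
#' @return Volume in µm³.
#' @examples
#' cell_volume(5, 5, 5) # sphere, 65.45
#' @export
cell_volume <- function(x, y, z) {
  if (any(c(x, y, z) <= 0)) stop("axis diameters must be > 0", call. = FALSE)
  4 / 3 * pi * (x / 2) * (y / 2) * (z / 2)
}

#' Default cytoplasm fraction of total cell volume
#'
#' About 67% of a yeast cell's volume is cytoplasm (the rest is nucleus,
#' vacuole and other organelles).
#' @export
CYTOPLASM_FRACTION <- 0.67

#' Molecules in the cytoplasm
#'
#' \eqn{N_{cyto} = V_{cell} \times f_{cyto} \times C_{cyto} \times N_A}
#' with volume in µm³ (1 µm³ = 1e-15 L) and concentration in µM.
#'
#' @param V_cell Cell volume, µm³.
#' @param C_cyto Cytoplasmic concentration, µM.
#' @param cyto_fraction Cytoplasm fraction of cell volume (default 0.67).
#' @return Molecule count (float; round for reporting).
#' @examples
#' molecules_in_cytoplasm(1, 1, cyto_fraction = 1) # ~602
#' @export
molecules_in_cytoplasm <- function(V_cell, C_cyto,
                                   cyto_fraction = CYTOPLASM_FRACTION) {
  stopifnot(V_cell >= 0, C_cyto >= 0, cyto_fraction > 0, cyto_fraction <= 1)
  V_cell * 1e-15 * cyto_fraction * C_cyto * 1e-6 * N_AVOGADRO
}

#' Molecules inside P bodies
#'
#' \eqn{N_{Pbody} = \sum_i \frac{\pi}{6} d_i^3 \, C_i \times N_A}, spheres
#' of diameter d (µm) at concentration C (µM).
#'
#' @param diameters Sphere diameters, µm.
#' @param concentrations Matching concentrations, µM.
#' @return Molecule count (float).
#' @export
molecules_in_pbodies <- function(diameters, concentrations) {
  if (length(diameters) != length(concentrations)) {
    stop("diameters and concentrations must have equal length", call. = FALSE)
  }
  if (!length(diameters)) return(0)
  stopifnot(all(diameters >= 0), all(concentrations >= 0))
  sum(pi / 6 * diameters^3 * 1e-15 * concentrations * 1e-6 * N_AVOGADRO)
}

#' Fraction of molecules sequestered in P bodies
#'
#' @param N_pbody,N_cyto Molecule counts.
#' @return \eqn{N_{Pbody} / (N_{cyto} + N_{Pbody})} in `[0, 1]`.
#' @export
fraction_in_pbodies <- function(N_pbody, N_cyto) {
  stopifnot(N_pbody >= 0, N_cyto >= 0)
  if (N_pbody + N_cyto == 0) {
    stop("both molecule counts are zero", call. = FALSE)
  }
  N_pbody / (N_cyto + N_pbody)
}

#' Upper-bound sequestration estimate F_P,max
#'
#' Visible P bodies undercount total condensate volume (many are below the
#' detection limit). Rescaling each protein's visible fraction by that of
#' the most sequestered reference protein (whose true fraction is taken as
#' one when small P bodies are accounted for) gives an upper bound:
#' \eqn{F_{P,max} = F_P / F_P(\mathrm{ref})}.
#'
#' @param f_p Fraction in P bodies for the protein of interest.
#' @param f_p_reference Fraction for the reference (most sequestered)
#'   protein; must be in (0, 1].
#' @return F_P,max; values above 1 are returned with a warning flag
#'   attribute `exceeds_one`.
#' @export
fp_max <- function(f_p, f_p_reference) {
  stopifnot(f_p >= 0, f_p <= 1)
  if (!is.numeric(f_p_reference) || f_p_reference <= 0 ||
      f_p_reference > 1) {
    stop("reference fraction must be in (0, 1]", call. = FALSE)
  }
  out <- f_p / f_p_reference
  attr(out, "exceeds_one") <- out > 1
  out
}

#' Average cellular concentration
#'
#' Total molecules (condensate + cytoplasm) over the cytoplasmic volume:
#' \eqn{(\sum V_P C_P + V_{cell} f_{cyto} C_{cyto}) / (V_{cell} f_{cyto})}.
#'
#' @param sum_VpCp Sum of P-body volume x concentration, µm³·µM.
#' @param V_cell Cell volume, µm³.
#' @param C_cyto Cytoplasmic concentration, µM.
#' @param cyto_fraction Cytoplasm fraction (default 0.67).
#' @return Concentration in µM.
#' @export
average_cellular_concentration <- function(sum_VpCp, V_cell, C_cyto,
                                           cyto_fraction = CYTOPLASM_FRACTION) {
  if (V_cell <= 0) stop("V_cell must be > 0", call. = FALSE)
  (sum_VpCp + V_cell * cyto_fraction * C_cyto) / (V_cell * cyto_fraction)
}

#' Per-cell sequestration bookkeeping
#'
#' Convenience wrapper combining the molecule-count operations for one cell.
#'
#' @param axes_um Named or positional cell axis diameters x, y, z in µm.
#' @param pbody_diameters,pbody_concentrations P bodies in the cell (µm, µM).
#' @param C_cyto Cytoplasmic concentration, µM.
#' @param cyto_fraction Cytoplasm fraction of cell volume.
#' @return A `sequestration_result`: `V_cell`, `V_pbodies`, `N_cyto`,
#'   `N_pbody`, `f_p`, `avg_cell_conc`.
#' @export
sequestration_result <- function(axes_um, pbody_diameters,
                                 pbody_concentrations, C_cyto,
                                 cyto_fraction = CYTOPLASM_FRACTION) {
  V_cell <- cell_volume(axes_um[[1]], axes_um[[2]], axes_um[[3]])
  V_p <- pi / 6 * pbody_diameters^3
  N_c <- molecules_in_cytoplasm(V_cell, C_cyto, cyto_fraction)
  N_p <- molecules_in_pbodies(pbody_diameters, pbody_concentrations)
  structure(list(
    V_cell = V_cell,
    V_pbodies = V_p,
    N_cyto = N_c,
    N_pbody = N_p,
    f_p = if (N_c + N_p > 0) fraction_in_pbodies(N_p, N_c) else NA_real_,
    avg_cell_conc = average_cellular_concentration(
      sum(V_p * pbody_concentrations), V_cell, C_cyto, cyto_fraction)),
    class = "sequestration_result")
}
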