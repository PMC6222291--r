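## Grid-parameter generation for Poisson-Boltzmann membrane-solvation
## calculations (APBSmem-style). Configuration only; no solver is run.

#' Grid specification from a PQR file
#'
#' The fine grid's z extent is chosen so the whole protein stays inside the
#' fine grid even when the membrane is scanned by +/- 20 Angstrom:
#' fine z = -2 * z_min + 40, with z_min the smallest z coordinate in the
#' PQR. Medium and coarse grids are 2x and 5x the fine grid componentwise;
#' the grid dimension is 161 points per axis. Mobile ions default to 150 mM
#' Na+ / Cl- with charges +1 / -1 and radii 0.95 / 1.81 Angstrom.
#'
#' @param pqr path to a PQR file (protein centered on the membrane frame,
#'   so z_min < 0), or a numeric vector of z coordinates.
#' @param fineXY numeric(2), fine-grid x and y extents taken from the
#'   solver input template (Angstrom).
#' @param membraneThickness bilayer thickness (Angstrom), e.g. from OPM.
#' @param zScanRange half-range of the membrane scan (Angstrom).
#' @return a [GridSpec-class].
#' @examples
#' gridFromPqr(c(-30, 10), fineXY = c(80, 90), membraneThickness = 30)
#' @export
gridFromPqr <- function(pqr, fineXY, membraneThickness, zScanRange = 20) {
  z <- if (is.numeric(pqr)) pqr else {
    if (!file.exists(pqr)) stop("PQR file not found: ", pqr)
    atoms <- bio3d::read.pqr(pqr)$atom
    if (is.null(atoms) || nrow(atoms) == 0L) stop("PQR file has no atoms: ", pqr)
    atoms$z
  }
  if (length(z) == 0L || !all(is.finite(z))) stop("no usable z coordinates in PQR input")
  zMin <- min(z)
  if (zMin >= 0)
    stop("z_min must be negative (protein centered on the membrane frame); got ",
         zMin)
  fine <- c(fineXY[1], fineXY[2], -2 * zMin + 40)
  new("GridSpec", fine = fine, medium = 2 * fine, coarse = 5 * fine,
      dimension = 161L, membraneThickness = as.numeric(membraneThickness),
      zScanRange = as.numeric(zScanRange),
      ions = data.frame(species = c("Na+", "Cl-"), charge = c(1, -1),
                        radius = c(0.95, 1.81), concentration = c(150, 150)))
}

#' Membrane z-scan plan
#'
#' Positions at which the bilayer is placed relative to its reference
#' (OPM) location: from -range to +range at the given step, always
#' including 0 (the reference placement).
#'
#' @param grid a [GridSpec-class].
#' @param step scan step in Angstrom (default 1).
#' @return numeric vector of z offsets (Angstrom).
#' @examples
#' length(emitScanPlan(gridFromPqr(c(-30), c(80, 80), 30))) # 41
#' @export
emitScanPlan <- function(grid, step = 1) {
  if (step <= 0) stop("scan step must be positive")
  r <- grid@zScanRange
  seq(-r, r, by = step)
}

#' Write a solver template and JSON for a GridSpec
#'
#' Emits a plain-text key=value template mirroring APBSmem-style input
#' fields, plus an optional JSON side-car of the full specification.
#'
#' @param grid a [GridSpec-class].
#' @param path output template file.
#' @param jsonPath optional JSON output file.
#' @export
writeGridTemplate <- function(grid, path, jsonPath = NULL) {
  fmt3 <- function(v) paste(format(v, trim = TRUE), collapse = " ")
  lines <- c(
    sprintf("dime %d %d %d", grid@dimension, grid@dimension, grid@dimension),
    sprintf("fglen %s", fmt3(grid@fine)),
    sprintf("mglen %s", fmt3(grid@medium)),
    sprintf("cglen %s", fmt3(grid@coarse)),
    sprintf("membrane_thickness %g", grid@membraneThickness),
    sprintf("z_scan_range %g", grid@zScanRange),
    sprintf("ion charge %g radius %g conc %g", grid@ions$charge,
            grid@ions$radius, grid@ions$concentration / 1000),
    "membrane_fill flooding"
  )
  writeLines(lines, path)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(
      fine = grid@fine, medium = grid@medium, coarse = grid@coarse,
      dimension = grid@dimension, membrane_thickness = grid@membraneThickness,
      z_scan_range = grid@zScanRange, ions = grid@ions,
      scan_positions = emitScanPlan(grid)
    ), jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
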