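## Protein tilt, membrane z-offsets, leaflet-bead membrane construction and
## cross-source placement comparison.

#' Principal axis of a Type I exporter
#'
#' The unit bisector of the normalized THX1 and THX2 conftor vectors (the
#' two TM-helix-pair cross-over vectors).
#'
#' @inheritParams computeConftor
#' @return unit numeric(3).
#' @export
principalAxis <- function(structure, annotation, membrane = NULL,
                          registry = builtinConftorRegistry(), model = 1L) {
  a <- .unit(conftorVector(computeConftor(structure, annotation, "THX1",
                                          membrane, registry, model)))
  b <- .unit(conftorVector(computeConftor(structure, annotation, "THX2",
                                          membrane, registry, model)))
  s <- a + b
  if (.norm3(s) < 1e-9)
    stop("THX1 and THX2 are antiparallel; the bisector is undefined")
  .unit(s)
}

#' Protein tilt angle in the membrane
#'
#' Angle between the membrane normal and the protein principal axis
#' (bisector of THX1/THX2), folded into [0, 90] degrees: an axis carries no
#' sign.
#'
#' @inheritParams computeConftor
#' @param membrane a [MembraneModel-class] (required).
#' @return degrees in [0, 90].
#' @export
tiltAngle <- function(structure, annotation, membrane,
                      registry = builtinConftorRegistry(), model = 1L) {
  axis <- principalAxis(structure, annotation, membrane, registry, model)
  ang <- vectorAngle(axis, membraneNormal(membrane))
  if (ang > 90) 180 - ang else ang
}

#' Membrane model from two leaflet bead sets
#'
#' For coarse-grained systems: the normal is the unit vector from the lower
#' to the upper leaflet phosphate/choline bead COG, the center their
#' midpoint, the thickness their separation.
#'
#' @param upperPoints,lowerPoints n x 3 matrices of bead coordinates
#'   (e.g. PO4 and NC3 beads of each leaflet).
#' @return a [MembraneModel-class].
#' @export
membraneFromLeaflets <- function(upperPoints, lowerPoints) {
  up <- .asPointMatrix(upperPoints); lo <- .asPointMatrix(lowerPoints)
  if (nrow(up) == 0L || nrow(lo) == 0L)
    stop("both leaflet bead sets must be non-empty")
  cu <- colMeans(up); cl <- colMeans(lo)
  sep <- cu - cl
  if (.norm3(sep) < 1e-9)
    stop("leaflet centers coincide; membrane normal is undefined")
  membraneModel(center = (cu + cl) / 2, normal = sep, thickness = .norm3(sep))
}

#' Leaflet bead coordinates from a bead structure file
#'
#' Reads PO4/NC3 (or user-named) beads from a plain-PDB bead file and
#' splits them into leaflets by the sign of their coordinate along a
#' provisional normal (z axis by default).
#'
#' @param structure a [ProteinStructure-class] holding the bead records.
#' @param beadNames atom names treated as leaflet beads.
#' @param model model index.
#' @return list with `upper` and `lower` coordinate matrices.
#' @export
leafletBeads <- function(structure, beadNames = c("PO4", "NC3"), model = 1L) {
  sel <- which(structure@atoms$elety %in% beadNames)
  if (length(sel) == 0L)
    stop("no leaflet beads (", paste(beadNames, collapse = "/"), ") found")
  pts <- modelCoords(structure, model)[sel, , drop = FALSE]
  zc <- pts[, 3] - mean(pts[, 3])
  list(upper = pts[zc > 0, , drop = FALSE], lower = pts[zc <= 0, , drop = FALSE])
}

#' Signed membrane-center offset along a reference normal
#'
#' Distance along the reference membrane normal between two membrane
#' centers (candidate minus reference). Both models must already be in the
#' same coordinate frame (superpose structures first).
#'
#' @param membrane candidate [MembraneModel-class].
#' @param referenceMembrane reference [MembraneModel-class].
#' @return signed offset in Angstrom.
#' @export
membraneZOffset <- function(membrane, referenceMembrane) {
  sum((membraneCenter(membrane) - membraneCenter(referenceMembrane)) *
        membraneNormal(referenceMembrane))
}

#' TM-helix COG offset from the membrane center
#'
#' Convenience variant: signed distance along the membrane normal between
#' the COG of all annotated TM-helix Calpha and the membrane center.
#'
#' @inheritParams computeConftor
#' @param membrane a [MembraneModel-class].
#' @return signed offset in Angstrom.
#' @export
tmCogOffset <- function(structure, annotation, membrane, model = 1L) {
  r <- regions(annotation)$region
  th <- r[grepl("^TH[0-9]+$", r)]
  if (length(th) == 0L) stop("no TM helices (TH*) annotated")
  cog <- centerOfGeometry(regionCa(structure, annotation, th, model))
  sum((cog - membraneCenter(membrane)) * membraneNormal(membrane))
}

#' Compare membrane placements across sources
#'
#' Tilt and z values from several placement sources (OPM, PDBTM, CG
#' simulation, ...) are compared to a reference source: tilt deltas are
#' non-negative magnitudes, z deltas signed.
#'
#' @param structureId structure identifier carried into the output.
#' @param placements data.frame with columns `source`, `tilt` (degrees),
#'   `z` (Angstrom).
#' @param referenceSource source name used as reference (default "OPM").
#' @return data.frame with columns `structure_id`, `source`, `tilt`, `z`,
#'   `tilt_delta`, `z_delta`; the reference row has zero deltas.
#' @export
comparePlacements <- function(structureId, placements, referenceSource = "OPM") {
  if (!referenceSource %in% placements$source)
    stop("reference source '", referenceSource, "' missing from placements")
  ref <- placements[placements$source == referenceSource, , drop = FALSE][1, ]
  data.frame(structure_id = structureId,
             source = placements$source,
             tilt = placements$tilt, z = placements$z,
             tilt_delta = abs(placements$tilt - ref$tilt),
             z_delta = placements$z - ref$z,
             stringsAsFactors = FALSE)
}
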