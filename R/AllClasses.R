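#' @import methods
NULL

.isUnit <- function(v, tol = 1e-9) abs(sqrt(sum(v^2)) - 1) <= tol

#' ProteinStructure: parsed atomic coordinates with one or more models
#'
#' Holds the per-atom metadata shared by all models (chain, author residue
#' number, insertion code, residue and atom names, ATOM/HETATM record type)
#' and one coordinate matrix per model. HETATM records (lipid beads, OPM
#' DUMMY atoms) are retained and can be selected via [dumAtoms()].
#'
#' @slot identifier character, e.g. a PDB ID or fixture name.
#' @slot atoms data.frame with columns `type`, `chain`, `resno`, `insert`,
#'   `resid`, `elety` (one row per atom).
#' @slot coords list of numeric n x 3 matrices, one per model, rows parallel
#'   to `atoms`.
#' @slot sourcePath character, where the structure was read from ("" for
#'   in-memory fixtures).
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(
    identifier = "character",
    atoms = "data.frame",
    coords = "list",
    sourcePath = "character"
  )
)

setValidity("ProteinStructure", function(object) {
  msgs <- character()
  need <- c("type", "chain", "resno", "insert", "resid", "elety")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (length(object@coords) < 1L)
    msgs <- c(msgs, "at least one model required")
  n <- nrow(object@atoms)
  if (n < 1L) msgs <- c(msgs, "every model must be non-empty")
  for (i in seq_along(object@coords)) {
    m <- object@coords[[i]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n)
      msgs <- c(msgs, sprintf("model %d coordinates must be a %d x 3 matrix", i, n))
    else if (!all(is.finite(m)))
      msgs <- c(msgs, sprintf("model %d contains non-finite coordinates", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' RegionAnnotation: named residue ranges per chain
#'
#' Region names follow the ABC Type I exporter vocabulary: TH1..TH12
#' (transmembrane helices), ICD1..ICD4 (intracellular domains), CH1..CH4
#' (coupling helices), WAH1/WAH2 (Walker A helices), SIG1/SIG2 (signature
#' motifs), S6_1/S6_2 and S9_1/S9_2 (NBD beta strands). Ranges are inclusive
#' in author numbering.
#'
#' @slot entries data.frame with columns `region`, `chain`, `start`, `end`.
#' @exportClass RegionAnnotation
setClass("RegionAnnotation", representation(entries = "data.frame"))

setValidity("RegionAnnotation", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("region", "chain", "start", "end")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    bad <- which(e$start > e$end)
    if (length(bad))
      msgs <- c(msgs, sprintf("start > end for region %s (row %d)", e$region[bad[1]], bad[1]))
    key <- paste(e$region, e$chain)
    if (anyDuplicated(key))
      msgs <- c(msgs, sprintf("duplicate region/chain: %s", key[duplicated(key)][1]))
  }
  if (length(msgs)) msgs else TRUE
})

#' MembraneModel: membrane center, normal and thickness
#'
#' @slot center numeric(3), membrane midplane center in Angstrom.
#' @slot normal numeric(3), unit vector pointing toward the extracellular
#'   side.
#' @slot thickness numeric(1), bilayer thickness in Angstrom (NA when
#'   unknown).
#' @exportClass MembraneModel
setClass("MembraneModel",
  representation(center = "numeric", normal = "numeric", thickness = "numeric"),
  prototype(thickness = NA_real_)
)

setValidity("MembraneModel", function(object) {
  msgs <- character()
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    msgs <- c(msgs, "center must be a finite 3-vector")
  if (length(object@normal) != 3L || !.isUnit(object@normal))
    msgs <- c(msgs, "normal must be a unit 3-vector (|n| = 1 within 1e-9)")
  if (length(object@thickness) != 1L)
    msgs <- c(msgs, "thickness must be a scalar")
  else if (!is.na(object@thickness) && object@thickness <= 0)
    msgs <- c(msgs, "thickness must be positive when present")
  if (length(msgs)) msgs else TRUE
})

#' AnchorSpec: how a conftor endpoint resolves to a point
#'
#' Kinds: `single_ca` (one Calpha), `cog_of_residues` (COG of all Calpha in
#' the target ranges), `cog_of_helix_ends` (COG of per-region terminal-end
#' anchors). Each target names a region, which end to use (`intracellular`,
#' `extracellular`, `whole`, or the sequence ends `first`/`last`) and a
#' window in residues (COG over the window when > 1).
#'
#' @slot kind character, one of the three anchor kinds.
#' @slot targets data.frame with columns `region`, `end`, `window`.
#' @exportClass AnchorSpec
setClass("AnchorSpec", representation(kind = "character", targets = "data.frame"))

setValidity("AnchorSpec", function(object) {
  kinds <- c("single_ca", "cog_of_residues", "cog_of_helix_ends")
  ends <- c("intracellular", "extracellular", "whole", "first", "last")
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    msgs <- c(msgs, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  t <- object@targets
  if (!all(c("region", "end", "window") %in% names(t)) || nrow(t) < 1L)
    msgs <- c(msgs, "targets must have >= 1 row with columns region, end, window")
  else {
    if (!all(t$end %in% ends))
      msgs <- c(msgs, paste("target end must be one of:", paste(ends, collapse = ", ")))
    if (any(t$window < 1L)) msgs <- c(msgs, "window must be >= 1")
    if (identical(object@kind, "single_ca") && (nrow(t) != 1L || t$window[1] != 1L))
      msgs <- c(msgs, "single_ca must have exactly one target with window 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConftorSpec: a named conftor definition (origin and tip anchors)
#'
#' @slot name character, e.g. "THX1".
#' @slot origin,tip [AnchorSpec-class] objects.
#' @slot orientation character, orientation class: "TH" conftors are
#'   forced to point intracellular to extracellular against the membrane
#'   normal, "IC" the reverse, "free" conftors are left as resolved.
#' @exportClass ConftorSpec
setClass("ConftorSpec",
  representation(name = "character", origin = "AnchorSpec", tip = "AnchorSpec",
                 orientation = "character"),
  prototype(orientation = "free")
)

setValidity("ConftorSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name)) return("name required")
  if (!object@orientation %in% c("TH", "IC", "free"))
    return("orientation must be TH, IC or free")
  TRUE
})

#' Conftor: a resolved conformational vector
#'
#' A directed segment from an origin anchor point to a tip anchor point;
#' the vector is tip - origin. Membrane-region conftors point from the
#' intracellular to the extracellular helix ends.
#'
#' @slot name character.
#' @slot origin,tip numeric(3) anchor points in Angstrom.
#' @exportClass Conftor
setClass("Conftor", representation(name = "character", origin = "numeric", tip = "numeric"))

setValidity("Conftor", function(object) {
  if (length(object@origin) != 3L || length(object@tip) != 3L ||
      !all(is.finite(c(object@origin, object@tip))))
    return("origin and tip must be finite 3-vectors")
  if (sqrt(sum((object@tip - object@origin)^2)) <= 0.5)
    return("origin and tip must be separated by > 0.5 Angstrom")
  TRUE
})

#' ConformationClass: result of nearest-prototype classification
#'
#' @slot label character, one of `bottom_open_inward_facing`,
#'   `bottom_closed_inward_facing`, `bottom_closed_outward_facing`,
#'   `occluded`.
#' @slot distances named numeric, Euclidean distance in (THX, ICV) angle
#'   space to each class prototype.
#' @slot ambiguityFlag logical, TRUE when the two best classes are closer
#'   than the ambiguity margin.
#' @exportClass ConformationClass
setClass("ConformationClass",
  representation(label = "character", distances = "numeric", ambiguityFlag = "logical")
)

setValidity("ConformationClass", function(object) {
  if (!object@label %in% rownames(conformationPrototypes()))
    return("unknown class label")
  TRUE
})

#' MetricSeries: one scalar metric tracked over coordinate frames
#'
#' @slot metricName character, e.g. "angle:THX1:THX2".
#' @slot frameIndices integer frame numbers.
#' @slot values numeric, degrees or Angstrom, one per frame.
#' @exportClass MetricSeries
setClass("MetricSeries",
  representation(metricName = "character", frameIndices = "integer", values = "numeric")
)

setValidity("MetricSeries", function(object) {
  if (length(object@frameIndices) != length(object@values))
    return("frameIndices and values must have equal length")
  TRUE
})

#' HelixGeometry: HELANAL-style helix descriptors
#'
#' Local helix axes are fitted to every 4 consecutive Calpha; a 9-residue
#' window pairs the local axes at its two ends (lag 5), whose angle is the
#' window's bending angle.
#'
#' @slot helixName character.
#' @slot windowAxes (n-8) x 3 matrix of unit window axes.
#' @slot bendingAngles numeric, degrees, one per window.
#' @slot maxBending numeric(1), degrees.
#' @slot overallAxis numeric(3) unit vector.
#' @slot twistPerResidue numeric(1), degrees.
#' @slot risePerResidue numeric(1), Angstrom.
#' @exportClass HelixGeometry
setClass("HelixGeometry",
  representation(helixName = "character", windowAxes = "matrix",
                 bendingAngles = "numeric", maxBending = "numeric",
                 overallAxis = "numeric", twistPerResidue = "numeric",
                 risePerResidue = "numeric")
)

setValidity("HelixGeometry", function(object) {
  if (any(object@bendingAngles < 0 | object@bendingAngles > 180))
    return("bending angles must lie in [0, 180] degrees")
  if (!.isUnit(object@overallAxis, 1e-6)) return("overallAxis must be a unit vector")
  TRUE
})

#' RigidTransform: proper rotation plus translation
#'
#' Applied as `x %*% t(rotation) + translation` to row-vector coordinates.
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform", representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L) return("translation must be a 3-vector")
  TRUE
})

#' GridSpec: Poisson-Boltzmann membrane-solvation grid parameters
#'
#' Fine, medium and coarse grid extents obey the fixed 1:2:5 componentwise
#' ratio; the grid dimension is identical on all axes.
#'
#' @slot fine,medium,coarse numeric(3) grid extents (x, y, z), Angstrom.
#' @slot dimension integer(1), grid points per axis.
#' @slot membraneThickness numeric(1), Angstrom.
#' @slot zScanRange numeric(1), half-range of the membrane z scan, Angstrom.
#' @slot ions data.frame with columns `charge`, `radius`, `concentration`
#'   (e, Angstrom, mM).
#' @exportClass GridSpec
setClass("GridSpec",
  representation(fine = "numeric", medium = "numeric", coarse = "numeric",
                 dimension = "integer", membraneThickness = "numeric",
                 zScanRange = "numeric", ions = "data.frame")
)

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (max(abs(object@medium - 2 * object@fine)) > 1e-9)
    msgs <- c(msgs, "medium grid must be 2 x fine, componentwise")
  if (max(abs(object@coarse - 5 * object@fine)) > 1e-9)
    msgs <- c(msgs, "coarse grid must be 5 x fine, componentwise")
  if (length(object@dimension) != 1L || object@dimension < 1L)
    msgs <- c(msgs, "dimension must be a single positive integer")
  if (length(msgs)) msgs else TRUE
})
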