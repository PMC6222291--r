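## Reading/writing structures and region annotations. PDB parsing is
## delegated to bio3d; this layer adds altloc resolution, multi-model
## bookkeeping and the validated S4 containers.

#' Construct a ProteinStructure from atom metadata and coordinates
#'
#' @param identifier structure identifier.
#' @param atoms data.frame with columns `type`, `chain`, `resno`, `insert`,
#'   `resid`, `elety`.
#' @param coords n x 3 matrix or list of such matrices (one per model).
#' @param sourcePath optional source file path.
#' @return a [ProteinStructure-class].
#' @export
proteinStructure <- function(identifier, atoms, coords, sourcePath = "") {
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; storage.mode(m) <- "double"; m
  })
  atoms$insert[is.na(atoms$insert)] <- ""
  new("ProteinStructure", identifier = as.character(identifier),
      atoms = as.data.frame(atoms), coords = coords,
      sourcePath = as.character(sourcePath))
}

#' Read a structure from PDB (or mmCIF)
#'
#' All ATOM records with resolvable coordinates are loaded; HETATM records
#' (lipid beads, OPM DUMMY atoms) are retained with `type == "HETATM"`.
#' Multi-model files expose every model unless `modelIndex` selects one.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken toward altloc "A").
#'
#' @param path PDB (.pdb/.ent) or mmCIF (.cif) file.
#' @param modelIndex optional single model to keep.
#' @param identifier identifier for the structure; default the file stem.
#' @return a [ProteinStructure-class].
#' @export
readStructure <- function(path, modelIndex = NULL, identifier = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(identifier))
    identifier <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path))
  iscif <- grepl("\\.cif(\\.gz)?$", path)
  if (!iscif) .checkCoordFields(path)
  pdb <- tryCatch(
    if (iscif) bio3d::read.cif(path) else
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) .badCoordError(path)
  )
  at <- pdb$atom
  nModel <- max(1L, nrow(pdb$xyz))
  ## altloc resolution: keep highest occupancy, ties -> 'A' (then first)
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  if (any(nzchar(alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[nzchar(alt)])) {
      idx <- which(key == k)
      if (length(idx) > 1L) {
        best <- idx[order(-occ[idx], alt[idx] != "A", alt[idx])][1]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
    xyzKeep <- bio3d::atom2xyz(which(keep))
  } else xyzKeep <- NULL
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (!is.null(xyzKeep)) xyz <- xyz[, xyzKeep, drop = FALSE]
  if (anyNA(xyz) || !all(is.finite(xyz))) .badCoordError(path)
  models <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  if (!is.null(modelIndex)) {
    modelIndex <- as.integer(modelIndex)
    if (modelIndex < 1L || modelIndex > length(models))
      stop("requested model ", modelIndex, " but file has ",
           length(models), " model(s): ", path)
    models <- models[modelIndex]
  }
  chain <- at$chain; chain[is.na(chain)] <- " "
  atoms <- data.frame(type = at$type, chain = chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, elety = at$elety,
                      stringsAsFactors = FALSE)
  proteinStructure(identifier, atoms, models, sourcePath = path)
}

## strict well-formedness check of PDB coordinate fields (columns 31-54);
## the delegated parser is lenient about trailing garbage in a field
.checkCoordFields <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    fields <- trimws(c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                       substr(lines[i], 47, 54)))
    ok <- grepl("^-?[0-9]*\\.?[0-9]+$", fields)
    if (!all(ok))
      stop("parse error in ", path, " line ", i,
           ": non-numeric coordinate field '", fields[!ok][1], "'")
  }
  invisible(TRUE)
}

## locate and cite the offending line when coordinates fail to parse
.badCoordError <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("parse error in ", path, " line ", i,
           ": non-numeric coordinate field in '", trimws(lines[i]), "'")
  }
  stop("parse error in ", path, ": unresolvable atom coordinates")
}

#' Write a structure to PDB
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file; multi-model structures are written with
#'   MODEL/ENDMDL records.
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  xyz <- do.call(rbind, lapply(structure@coords, function(m) as.numeric(t(m))))
  chain <- a$chain
  chain[!nzchar(trimws(chain))] <- " "
  bio3d::write.pdb(file = path, type = a$type, xyz = xyz,
                   resno = a$resno, resid = a$resid, insert = a$insert,
                   chain = chain, elety = a$elety)
  invisible(path)
}

#' DUMMY membrane atoms of an OPM-flavored structure
#'
#' @param structure a [ProteinStructure-class].
#' @param model model index.
#' @return n x 3 coordinate matrix of residues named `DUM`.
#' @export
dumAtoms <- function(structure, model = 1L) {
  sel <- which(structure@atoms$resid == "DUM")
  modelCoords(structure, model)[sel, , drop = FALSE]
}

#' Construct a MembraneModel
#'
#' @param center numeric(3), Angstrom.
#' @param normal numeric(3); normalized internally.
#' @param thickness bilayer thickness in Angstrom, or NA.
#' @return a [MembraneModel-class].
#' @export
membraneModel <- function(center = c(0, 0, 0), normal = c(0, 0, 1), thickness = NA_real_) {
  new("MembraneModel", center = as.numeric(center), normal = .unit(as.numeric(normal)),
      thickness = as.numeric(thickness))
}

#' Derive a MembraneModel from OPM DUMMY atoms
#'
#' OPM entries mark the two membrane boundary planes with pseudo-atoms of
#' residue name DUM. The center is the COG of all DUMMY atoms; the normal
#' is the (averaged) unit normal of the best-fit plane of each layer,
#' oriented toward the layer with the greater mean z; the thickness is the
#' separation of the two layer planes along the normal. Layers are split by
#' the sign of z after centering.
#'
#' @param structure a [ProteinStructure-class] containing DUM records.
#' @param model model index.
#' @return a [MembraneModel-class].
#' @export
parseOpmMembrane <- function(structure, model = 1L) {
  d <- dumAtoms(structure, model)
  if (nrow(d) == 0L)
    stop("no membrane annotation: structure '", structure@identifier,
         "' has no DUM residues")
  center <- colMeans(d)
  zc <- d[, 3] - center[3]
  up <- d[zc > 0, , drop = FALSE]
  lo <- d[zc <= 0, , drop = FALSE]
  if (nrow(up) < 3L || nrow(lo) < 3L)
    stop("membrane DUMMY atoms form only one layer; two boundary planes required")
  nUp <- .planeNormal(up); nLo <- .planeNormal(lo)
  if (sum(nUp * nLo) < 0) nLo <- -nLo
  normal <- .unit(nUp + nLo)
  if (normal[3] < 0) normal <- -normal          # toward greater mean z
  thickness <- abs(sum((colMeans(up) - colMeans(lo)) * normal))
  membraneModel(center, normal, thickness)
}

## least-squares plane normal (smallest principal direction)
.planeNormal <- function(points) {
  c0 <- sweep(points, 2L, colMeans(points))
  s <- svd(c0)
  .unit(s$v[, 3])
}

#' Construct a RegionAnnotation
#'
#' @param entries data.frame with columns `region`, `chain`, `start`,
#'   `end` (inclusive, author numbering).
#' @return a [RegionAnnotation-class].
#' @export
regionAnnotation <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$region <- as.character(entries$region)
  entries$chain <- as.character(entries$chain)
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  rownames(entries) <- NULL
  new("RegionAnnotation", entries = entries)
}

#' Load a region annotation from TSV
#'
#' Expects a header row with columns `region_name`, `chain`, `start`,
#' `end` (tab-separated). Ranges are inclusive in author numbering.
#'
#' @param path TSV file.
#' @return a [RegionAnnotation-class].
#' @export
loadAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("region_name", "chain", "start", "end")
  unknown <- setdiff(names(df), need)
  if (length(unknown))
    stop("unknown annotation column(s): ", paste(unknown, collapse = ", "),
         " (expected ", paste(need, collapse = ", "), ")")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("annotation start/end must be integers")
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("annotation row ", bad[1], " (", df$region_name[bad[1]],
         "): start ", df$start[bad[1]], " > end ", df$end[bad[1]])
  key <- paste(df$region_name, df$chain)
  if (anyDuplicated(key))
    stop("duplicate annotation for region/chain: ", key[duplicated(key)][1])
  regionAnnotation(data.frame(region = df$region_name, chain = df$chain,
                              start = df$start, end = df$end,
                              stringsAsFactors = FALSE))
}

#' Validate that an annotation covers the regions a conftor set needs
#'
#' @param annotation a [RegionAnnotation-class].
#' @param specs list of [ConftorSpec-class] objects (or a single one).
#' @return invisibly TRUE; errors naming the first missing region.
#' @export
validateAnnotation <- function(annotation, specs) {
  if (is(specs, "ConftorSpec")) specs <- list(specs)
  have <- regions(annotation)$region
  for (sp in specs) {
    needed <- c(sp@origin@targets$region, sp@tip@targets$region)
    miss <- setdiff(needed, have)
    if (length(miss))
      stop("conftor ", sp@name, " requires unannotated region(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
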