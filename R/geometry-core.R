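## Vector and rigid-body primitives. Coordinates are row-vector matrices
## (n x 3, Angstrom) throughout.

.asPointMatrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("point matrix must have 3 columns")
    points
  } else if (is.numeric(points) && length(points) == 3L) {
    matrix(points, 1L, 3L)
  } else if (is.list(points)) {
    do.call(rbind, lapply(points, function(p) {
      if (length(p) != 3L) stop("each point must be a 3-vector")
      as.numeric(p)
    }))
  } else stop("points must be an n x 3 matrix, a 3-vector, or a list of 3-vectors")
}

.norm3 <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .norm3(v)
  if (n == 0) stop("cannot normalize a zero-length vector")
  v / n
}

#' Center of geometry of a point set
#'
#' Unweighted arithmetic mean of coordinates.
#'
#' @param points n x 3 matrix (or 3-vector, or list of 3-vectors), Angstrom.
#' @return numeric(3).
#' @examples
#' centerOfGeometry(rbind(c(0, 0, 0), c(2, 2, 2)))
#' @export
centerOfGeometry <- function(points) {
  p <- .asPointMatrix(points)
  if (nrow(p) == 0L) stop("center of geometry of an empty point set is undefined")
  colMeans(p)
}

#' Angle between two vectors, in degrees
#'
#' The dot product is clipped to [-1, 1] before `acos` to absorb
#' floating-point overshoot; the result lies in [0, 180] and is symmetric
#' in its arguments.
#'
#' @param a,b nonzero numeric 3-vectors.
#' @return angle in degrees.
#' @examples
#' vectorAngle(c(1, 0, 0), c(1, 1, 0)) # 45
#' @export
vectorAngle <- function(a, b) {
  na <- .norm3(a); nb <- .norm3(b)
  if (na == 0 || nb == 0) stop("vectorAngle is undefined for a zero-length vector")
  d <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation numeric(3).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Apply a RigidTransform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points n x 3 matrix or 3-vector.
#' @return transformed coordinates, same shape class as a matrix.
#' @export
applyTransform <- function(transform, points) {
  p <- .asPointMatrix(points)
  sweep(p %*% t(transform@rotation), 2L, -transform@translation)
}

#' Kabsch superposition of one point set onto another
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` (reflections excluded) via singular value
#' decomposition of the cross-covariance matrix.
#'
#' @param mobile,reference equal-length n x 3 matrices, n >= 3,
#'   non-collinear.
#' @return list with `transform` (a [RigidTransform-class]) and `rmsd`
#'   (Angstrom, the minimized value).
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' kabschSuperpose(ref, ref)$rmsd # 0
#' @export
kabschSuperpose <- function(mobile, reference) {
  m <- .asPointMatrix(mobile); r <- .asPointMatrix(reference)
  if (nrow(m) != nrow(r))
    stop("mobile and reference must have the same number of points (",
         nrow(m), " vs ", nrow(r), ")")
  if (nrow(m) < 3L) stop("superposition requires at least 3 points")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2L, cm); rc <- sweep(r, 2L, cr)
  # collinearity: rank of the centered set < 2
  sv <- svd(mc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) point set: superposition is ill-defined")
  H <- crossprod(mc, rc)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- cr - as.numeric(R %*% cm)
  fitted <- sweep(mc %*% t(R), 2L, -cr)
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  list(transform = rigidTransform(R, translation), rmsd = rmsd)
}

#' Calpha coordinates for annotated regions
#'
#' Resolves the Calpha atoms of one or more annotated regions, in region
#' order then residue order. A missing Calpha at a range end is substituted
#' by the nearest resolved residue within 2 positions inward (with a
#' warning); interior gaps are skipped only for whole-region selections.
#'
#' @param structure a [ProteinStructure-class].
#' @param annotation a [RegionAnnotation-class].
#' @param regionNames character vector of region names.
#' @param model model index.
#' @return n x 3 coordinate matrix.
#' @export
regionCa <- function(structure, annotation, regionNames, model = 1L) {
  e <- regions(annotation)
  out <- vector("list", length(regionNames))
  for (i in seq_along(regionNames)) {
    row <- e[e$region == regionNames[i], , drop = FALSE]
    if (nrow(row) == 0L)
      stop("region '", regionNames[i], "' is not annotated")
    out[[i]] <- .caRange(structure, row$chain[1], row$start[1], row$end[1], model)
  }
  do.call(rbind, out)
}

## all resolved Calpha in [start, end]; NULL rows dropped
.caRange <- function(structure, chain, start, end, model = 1L) {
  a <- structure@atoms
  xyz <- modelCoords(structure, model)
  sel <- which(a$chain == chain & a$elety == "CA" & a$resno >= start & a$resno <= end)
  if (length(sel) == 0L)
    stop("no Calpha atoms for chain ", chain, " residues ", start, "-", end,
         " in structure '", structure@identifier, "'")
  sel <- sel[order(a$resno[sel], a$insert[sel])]
  xyz[sel, , drop = FALSE]
}

## single Calpha with inward substitution (design rule: <= 2 positions)
.caSingle <- function(structure, chain, resno, model = 1L, inwardStep = 0L) {
  a <- structure@atoms
  xyz <- modelCoords(structure, model)
  for (off in 0:2) {
    r <- resno + off * inwardStep
    sel <- which(a$chain == chain & a$elety == "CA" & a$resno == r)
    if (length(sel)) {
      if (off > 0L)
        warning("Calpha for chain ", chain, " residue ", resno,
                " missing; substituted residue ", r, call. = FALSE)
      return(xyz[sel[1], ])
    }
    if (inwardStep == 0L) break
  }
  stop("no Calpha within 2 residues of chain ", chain, " residue ", resno,
       " in structure '", structure@identifier, "'")
}

#' Pairwise Kabsch RMSD matrix over a common annotated core
#'
#' @param structures list of [ProteinStructure-class] objects.
#' @param annotations a single [RegionAnnotation-class] (shared) or a list,
#'   one per structure.
#' @param regionNames regions defining the Calpha selection; default all
#'   annotated TM helices (names starting "TH").
#' @param model model index used for every structure.
#' @return symmetric matrix of RMSD values (Angstrom) with structure
#'   identifiers as dimnames; zero diagonal.
#' @export
pairwiseRmsdMatrix <- function(structures, annotations, regionNames = NULL, model = 1L) {
  n <- length(structures)
  if (!is.list(annotations) || is(annotations, "RegionAnnotation"))
    annotations <- rep(list(annotations), n)
  if (length(annotations) != n)
    stop("need one annotation per structure (or a single shared one)")
  if (is.null(regionNames)) {
    regionNames <- Reduce(intersect, lapply(annotations, function(a) {
      r <- regions(a)$region
      r[grepl("^TH[0-9]+$", r)]
    }))
    if (length(regionNames) == 0L) stop("no shared TM-helix regions to select")
  }
  sets <- lapply(seq_len(n), function(i)
    regionCa(structures[[i]], annotations[[i]], regionNames, model))
  lens <- vapply(sets, nrow, integer(1))
  if (length(unique(lens)) > 1L) {
    ids <- vapply(structures, identifier, character(1))
    stop("selection resolves to unequal Calpha counts: ",
         paste(sprintf("%s=%d", ids, lens), collapse = ", "))
  }
  m <- matrix(0, n, n)
  ids <- vapply(structures, identifier, character(1))
  dimnames(m) <- list(ids, ids)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- kabschSuperpose(sets[[i]], sets[[j]])$rmsd
  }
  m
}

#' Write an RMSD matrix as labelled TSV
#'
#' @param m matrix from [pairwiseRmsdMatrix()].
#' @param path output file.
#' @export
writeRmsdMatrix <- function(m, path) {
  df <- data.frame(structure_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
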