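## HELANAL-style helix geometry from Calpha traces, plus 2D projection of
## helix end positions onto the membrane plane.

#' HELANAL-style geometry of a helix Calpha trace
#'
#' Local helix axes are computed for every 4 consecutive Calpha from the
#' cross product of successive second-difference (radially inward) vectors
#' and oriented along the chain direction. A 9-residue sliding window pairs
#' the local axes at its two ends (lag 5): their angle is the window's
#' bending angle, and the unit mean of the six local axes inside the window
#' is the window axis. Twist per residue comes from the angle between
#' successive second-difference vectors, rise per residue from the
#' projection of the Calpha step onto the local axis.
#'
#' @param caCoords ordered n x 3 matrix of Calpha positions, n >= 9.
#' @param helixName label carried into the result.
#' @return a [HelixGeometry-class].
#' @examples
#' h <- makeIdealHelix(30)
#' helanalGeometry(h)
#' @export
helanalGeometry <- function(caCoords, helixName = "helix") {
  p <- .asPointMatrix(caCoords)
  n <- nrow(p)
  if (n < 9L) stop("HELANAL geometry requires >= 9 Calpha positions (got ", n, ")")
  d <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]        # n-1 steps
  s <- d[-1, , drop = FALSE] - d[-(n - 1L), , drop = FALSE] # n-2 second diffs
  chainDir <- p[n, ] - p[1, ]
  nAxes <- n - 3L                                           # one per 4 Calpha
  axes <- matrix(0, nAxes, 3L)
  twists <- rises <- numeric(nAxes)
  for (i in seq_len(nAxes)) {
    a <- .unit(.cross3(s[i, ], s[i + 1L, ]))
    if (sum(a * chainDir) < 0) a <- -a
    axes[i, ] <- a
    twists[i] <- vectorAngle(s[i, ], s[i + 1L, ])
    rises[i] <- abs(sum(d[i + 1L, ] * a))
  }
  nWin <- n - 8L                                            # 9-residue windows
  bending <- numeric(nWin)
  winAxes <- matrix(0, nWin, 3L)
  for (w in seq_len(nWin)) {
    bending[w] <- vectorAngle(axes[w, ], axes[w + 5L, ])
    winAxes[w, ] <- .unit(colSums(axes[w:(w + 5L), , drop = FALSE]))
  }
  overall <- .unit(colSums(axes))
  new("HelixGeometry", helixName = helixName, windowAxes = winAxes,
      bendingAngles = bending, maxBending = max(bending),
      overallAxis = overall, twistPerResidue = mean(twists),
      risePerResidue = mean(rises))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Detect helix breaks from bending angles
#'
#' @param geometry a [HelixGeometry-class].
#' @param threshold bending angle above which a window is reported
#'   (degrees, default 20).
#' @return data.frame with columns `window` (index of the 9-residue
#'   window) and `bending` (degrees), sorted by decreasing bending; zero
#'   rows when no window exceeds the threshold.
#' @export
detectBreaks <- function(geometry, threshold = 20) {
  hit <- which(geometry@bendingAngles > threshold)
  out <- data.frame(window = hit, bending = geometry@bendingAngles[hit])
  out[order(-out$bending), , drop = FALSE]
}

#' Orthonormal in-plane basis of a membrane plane
#'
#' Deterministic: the first axis is the projection of the lab x axis (or y
#' when x is near-parallel to the normal) into the plane; the second
#' completes a right-handed frame with the normal.
#'
#' @param membrane a [MembraneModel-class].
#' @return 2 x 3 matrix of unit in-plane axes.
#' @export
membranePlaneBasis <- function(membrane) {
  nrm <- membraneNormal(membrane)
  seedAxis <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(seedAxis - sum(seedAxis * nrm) * nrm)
  e2 <- .cross3(nrm, e1)
  rbind(e1, e2)
}

#' Project TM helix end positions onto the membrane plane
#'
#' Each annotated TM helix contributes two end anchors (intracellular and
#' extracellular terminal Calpha). Anchors are projected onto the plane
#' through the membrane center orthogonal to the normal and expressed in
#' the plane's 2D basis. When a reference structure is given, the structure
#' is first superposed onto it over the shared annotated Calpha core, and
#' the reference's membrane frame is used, making projections comparable
#' across structures.
#'
#' @param structure a [ProteinStructure-class].
#' @param annotation a [RegionAnnotation-class].
#' @param membrane a [MembraneModel-class] for `structure`.
#' @param reference optional [ProteinStructure-class] to superpose onto.
#' @param referenceAnnotation annotation of the reference (required with
#'   `reference`).
#' @param referenceMembrane membrane of the reference (defaults to
#'   `membrane`).
#' @param regionNames helices to project; default all regions named
#'   TH<number>.
#' @param model model index.
#' @return data.frame with columns `helix`, `side`
#'   (intracellular/extracellular), `x`, `y` (Angstrom).
#' @export
projectHelixEnds <- function(structure, annotation, membrane, reference = NULL,
                             referenceAnnotation = NULL, referenceMembrane = NULL,
                             regionNames = NULL, model = 1L) {
  if (is.null(membrane)) stop("a membrane model is required for end projection")
  if (is.null(regionNames)) {
    r <- regions(annotation)$region
    regionNames <- r[grepl("^TH[0-9]+$", r)]
    if (length(regionNames) == 0L) stop("no TM helices (TH*) annotated")
  }
  frameMembrane <- membrane
  transform <- NULL
  if (!is.null(reference)) {
    if (is.null(referenceAnnotation))
      stop("referenceAnnotation is required when superposing to a reference")
    shared <- intersect(regions(annotation)$region,
                        regions(referenceAnnotation)$region)
    mob <- regionCa(structure, annotation, shared, model)
    ref <- regionCa(reference, referenceAnnotation, shared)
    transform <- kabschSuperpose(mob, ref)$transform
    frameMembrane <- if (is.null(referenceMembrane)) membrane else referenceMembrane
  }
  basis <- membranePlaneBasis(frameMembrane)
  ctr <- membraneCenter(frameMembrane)
  rows <- list()
  for (h in regionNames) {
    for (side in c("intracellular", "extracellular")) {
      pt <- .endAnchor(structure, annotation, h, side, 1L, membrane, model)
      if (!is.null(transform)) pt <- as.numeric(applyTransform(transform, pt))
      rel <- pt - ctr
      rows[[length(rows) + 1L]] <- data.frame(
        helix = h, side = side,
        x = sum(rel * basis[1, ]), y = sum(rel * basis[2, ]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare two helix-end projection sets
#'
#' Both sets must come from structures superposed to a common reference
#' frame and contain the same helix/side keys.
#'
#' @param a,b data.frames from [projectHelixEnds()].
#' @param outlierThreshold in-plane displacement above which an end is
#'   flagged (Angstrom, default 5).
#' @return data.frame with columns `helix`, `side`, `displacement`
#'   (Angstrom) and `outlier` (logical).
#' @export
compareEndProjections <- function(a, b, outlierThreshold = 5) {
  keyA <- paste(a$helix, a$side); keyB <- paste(b$helix, b$side)
  if (!setequal(keyA, keyB) || anyDuplicated(keyA) || anyDuplicated(keyB))
    stop("projection sets must contain the same helix/side keys exactly once")
  b <- b[match(keyA, keyB), , drop = FALSE]
  disp <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  data.frame(helix = a$helix, side = a$side, displacement = disp,
             outlier = disp > outlierThreshold, stringsAsFactors = FALSE)
}

#' Scatter plot of helix-end projections
#'
#' Intracellular and extracellular ends are drawn side by side in the
#' membrane-plane frame; useful for spotting displaced helices.
#'
#' @param projections data.frame from [projectHelixEnds()] (optionally with
#'   an extra `structure_id` column to overlay several structures).
#' @param ... passed to [graphics::plot()].
#' @export
plotEndProjections <- function(projections, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (side in c("intracellular", "extracellular")) {
    p <- projections[projections$side == side, , drop = FALSE]
    graphics::plot(p$x, p$y, xlab = "x (A)", ylab = "y (A)",
                   main = paste(side, "ends"), pch = 19, ...)
    graphics::text(p$x, p$y, labels = p$helix, pos = 3, cex = 0.7)
  }
  invisible(NULL)
}
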