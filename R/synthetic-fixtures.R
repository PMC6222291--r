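## Ground-truth fixture generators: ideal and kinked helices, OPM-style
## DUMMY membranes, leaflet bead planes, and a parameterized toy Type I
## transporter whose conftor geometry is known by construction. The
## pseudo-helices are geometric Calpha traces (not chemically valid
## proteins); every implemented metric consumes Calpha only, so this is
## sufficient for exact parameter-recovery testing.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis rotation axis (normalized internally).
#' @param degrees rotation angle.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotationAboutAxis <- function(axis, degrees) {
  u <- .unit(as.numeric(axis))
  th <- degrees * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## rotation mapping the lab z axis onto `axis`
.rotationFromZ <- function(axis) {
  a <- .unit(as.numeric(axis))
  z <- c(0, 0, 1)
  c3 <- .cross3(z, a)
  if (.norm3(c3) < 1e-12) {
    if (sum(z * a) > 0) return(diag(3))
    return(rotationAboutAxis(c(1, 0, 0), 180))
  }
  rotationAboutAxis(c3, acos(max(-1, min(1, sum(z * a)))) * 180 / pi)
}

#' Calpha trace of an ideal alpha helix
#'
#' Calpha on a helix of the given radius about `axis`, with the first
#' residue nearest `origin` (the helix axis passes through `origin`).
#'
#' @param nRes number of residues (>= 4).
#' @param axis helix axis direction.
#' @param origin axis point of the first residue.
#' @param rise rise per residue (Angstrom, default 1.5).
#' @param twist twist per residue (degrees, default 100).
#' @param radius helix radius (Angstrom, default 2.3).
#' @param phase phase of the first residue (degrees).
#' @return nRes x 3 matrix of Calpha coordinates.
#' @export
makeIdealHelix <- function(nRes, axis = c(0, 0, 1), origin = c(0, 0, 0),
                           rise = 1.5, twist = 100, radius = 2.3, phase = 0) {
  if (nRes < 4L) stop("an ideal helix fixture needs >= 4 residues")
  i <- seq_len(nRes) - 1
  th <- (phase + i * twist) * pi / 180
  local <- cbind(radius * cos(th), radius * sin(th), i * rise)
  R <- .rotationFromZ(axis)
  sweep(local %*% t(R), 2L, -as.numeric(origin))
}

#' Calpha trace of a kinked helix
#'
#' Two ideal arms sharing rise/twist/radius whose axes enclose `kinkAngle`
#' at the junction: an ideal helix of n1 + n2 residues is built and the
#' second arm is rotated about an in-plane axis through the junction point
#' of the helix axis. A kink of 0 degrees reproduces the ideal helix
#' exactly.
#'
#' @param n1,n2 residues per arm (each >= 9).
#' @param kinkAngle kink angle in degrees (< 170; 180 would fold the helix
#'   back onto itself).
#' @param rise,twist,radius,phase as in [makeIdealHelix()].
#' @return (n1 + n2) x 3 matrix of Calpha coordinates.
#' @export
makeKinkedHelix <- function(n1, n2, kinkAngle, rise = 1.5, twist = 100,
                            radius = 2.3, phase = 0) {
  if (n1 < 9L || n2 < 9L) stop("each kinked-helix arm needs >= 9 residues")
  if (kinkAngle < 0 || kinkAngle >= 170)
    stop("kink angle must lie in [0, 170) degrees (fold-back is degenerate)")
  p <- makeIdealHelix(n1 + n2, rise = rise, twist = twist, radius = radius,
                      phase = phase)
  pivot <- c(0, 0, (n1 - 0.5) * rise)
  R <- rotationAboutAxis(c(1, 0, 0), kinkAngle)
  arm2 <- seq(n1 + 1L, n1 + n2)
  p[arm2, ] <- sweep(sweep(p[arm2, , drop = FALSE], 2L, pivot) %*% t(R), 2L, -pivot)
  p
}

## straight Calpha rod: geometric pseudo-helix used by the toy transporter
.rodCa <- function(start, direction, nRes, spacing = 1.5) {
  d <- .unit(as.numeric(direction))
  t(vapply(seq_len(nRes) - 1, function(i) as.numeric(start) + i * spacing * d,
           numeric(3)))
}

## rod centered on `center`
.rodCentered <- function(center, direction, nRes, spacing = 1.5) {
  d <- .unit(as.numeric(direction))
  .rodCa(as.numeric(center) - (nRes - 1) / 2 * spacing * d, d, nRes, spacing)
}

#' OPM-style membrane structure of DUMMY atoms
#'
#' Two square grids of HETATM records with residue name DUM marking the
#' membrane boundary planes, as in OPM-deposited PDB files.
#'
#' @param center membrane center, Angstrom.
#' @param normal membrane normal.
#' @param thickness bilayer thickness, Angstrom.
#' @param halfWidth in-plane half-extent of the grids, Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @return a [ProteinStructure-class] of DUM atoms only.
#' @export
makeOpmMembraneStructure <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                                     thickness = 30, halfWidth = 36, spacing = 12) {
  pts <- .dumGrid(center, normal, thickness, halfWidth, spacing)
  atoms <- data.frame(type = "HETATM", chain = "M",
                      resno = 9000L + seq_len(nrow(pts)), insert = "",
                      resid = "DUM", elety = "DUM", stringsAsFactors = FALSE)
  proteinStructure("synthetic-membrane", atoms, pts)
}

.dumGrid <- function(center, normal, thickness, halfWidth = 36, spacing = 12) {
  nrm <- .unit(as.numeric(normal))
  basis <- membranePlaneBasis(membraneModel(center, nrm))
  g <- seq(-halfWidth, halfWidth, by = spacing)
  inplane <- as.matrix(expand.grid(u = g, v = g))
  layer <- function(sgn) {
    t(apply(inplane, 1L, function(uv)
      as.numeric(center) + uv[1] * basis[1, ] + uv[2] * basis[2, ] +
        sgn * thickness / 2 * nrm))
  }
  rbind(layer(+1), layer(-1))
}

#' Toy-transporter parameters
#'
#' Defaults describe a bottom-open inward-facing exporter: THX1/THX2 angle
#' 46 degrees, ICV1/ICV2 angle 43 degrees, NBD-bottom (S9-S9) separation
#' 50 Angstrom, NBD/TMD-interface (coupling-helix COG) separation 40
#' Angstrom, no tilt, in a 30 Angstrom membrane.
#'
#' @param thxAngle,icvAngle ground-truth conftor angles, degrees.
#' @param thvAngle ground-truth THV1/THV2 angle, degrees; defaults to
#'   `thxAngle`. When it differs, the TH4/TH5 (and TH10/TH11) directions
#'   are split symmetrically about the THX direction so that both angles
#'   hold exactly.
#' @param nbdIntDistance,nbdExtDistance ground-truth NBDX int/ext
#'   distances, Angstrom.
#' @param tilt protein tilt in the membrane, degrees.
#' @param seed integer seed (generation is deterministic; the seed feeds
#'   optional coordinate jitter).
#' @param jitter Gaussian coordinate noise sd, Angstrom (0 = exact
#'   ground truth).
#' @return named list of parameters.
#' @export
toyTransporterParams <- function(thxAngle = 46, icvAngle = 43,
                                 thvAngle = thxAngle,
                                 nbdIntDistance = 50, nbdExtDistance = 40,
                                 tilt = 0, seed = 1L, jitter = 0) {
  list(thxAngle = thxAngle, icvAngle = icvAngle, thvAngle = thvAngle,
       nbdIntDistance = nbdIntDistance, nbdExtDistance = nbdExtDistance,
       tilt = tilt, seed = as.integer(seed), jitter = jitter)
}

## region layout of the toy transporter: name -> (start, nRes)
.toyLayout <- function() {
  th <- lapply(1:12, function(k) list(start = 100L + (k - 1L) * 25L, n = 21L))
  names(th) <- paste0("TH", 1:12)
  icd <- lapply(1:4, function(d) list(start = 500L + (d - 1L) * 20L, n = 11L))
  names(icd) <- paste0("ICD", 1:4)
  ch <- lapply(1:4, function(c) list(start = 600L + (c - 1L) * 10L, n = 7L))
  names(ch) <- paste0("CH", 1:4)
  rest <- list(WAH1 = list(start = 700L, n = 7L), WAH2 = list(start = 710L, n = 7L),
               SIG1 = list(start = 720L, n = 5L), SIG2 = list(start = 730L, n = 5L),
               S6_1 = list(start = 740L, n = 5L), S6_2 = list(start = 750L, n = 5L),
               S9_1 = list(start = 760L, n = 5L), S9_2 = list(start = 770L, n = 5L))
  c(th, icd, ch, rest)
}

#' Generate a toy Type I transporter with known conftor geometry
#'
#' Builds a 12-pseudo-helix assembly in which the THX1/THX2 and ICV1/ICV2
#' angles, the NBDX ext/int distances, and the membrane tilt take exactly
#' the requested values: TH4/TH5 and TH10/TH11 are parallel straight
#' Calpha rods enclosing `thxAngle`; ICD1/ICD2 and ICD3/ICD4 continue them
#' below the membrane enclosing `icvAngle`; coupling-helix COGs and S9
#' first residues realize the ext/int distances; the whole protein (but
#' not the membrane) is then tilted about the x axis. An OPM-style DUMMY
#' membrane is included in the structure.
#'
#' @param params list from [toyTransporterParams()].
#' @return list with elements `structure` ([ProteinStructure-class],
#'   including DUM atoms), `annotation` ([RegionAnnotation-class]),
#'   `membrane` ([MembraneModel-class]) and `truth` (named list of
#'   ground-truth metric values).
#' @export
makeToyTransporter <- function(params = toyTransporterParams()) {
  thx <- params$thxAngle; icv <- params$icvAngle; tilt <- params$tilt
  thv <- if (is.null(params$thvAngle)) thx else params$thvAngle
  ext <- params$nbdExtDistance; int <- params$nbdIntDistance
  if (!is.finite(thx) || thx <= 0 || thx >= 178)
    stop("infeasible thxAngle: ", thx, " (need 0 < angle < 178)")
  if (!is.finite(icv) || icv <= 0 || icv >= 170)
    stop("infeasible icvAngle: ", icv, " (need 0 < angle < 170)")
  if (ext <= 0 || int <= 0) stop("NBD distances must be positive")
  if (thx / 2 + abs(tilt) >= 85 || icv / 2 + abs(tilt) >= 85)
    stop("infeasible combination: tilt ", tilt,
         " with the requested angles would lay helices into the membrane plane")
  ## TH4 sits at thv/2 from the axis, TH5 at thx - thv/2, so the THX
  ## direction (their bisector) encloses thx while THV1/THV2 enclose thv
  cA <- thv / 2 * pi / 180
  cB <- (thx - thv / 2) * pi / 180
  if (abs(cB) * 180 / pi + abs(tilt) >= 85 || abs(cA) * 180 / pi + abs(tilt) >= 85)
    stop("infeasible thvAngle ", thv, " for thxAngle ", thx, " at tilt ", tilt)
  a <- thx / 2 * pi / 180
  b <- icv / 2 * pi / 180
  v4 <- c(sin(cA), 0, cos(cA)); v5 <- c(sin(cB), 0, cos(cB))
  v10 <- c(-sin(cA), 0, cos(cA)); v11 <- c(-sin(cB), 0, cos(cB))
  u1 <- c(sin(a), 0, cos(a)); u2 <- c(-sin(a), 0, cos(a))
  w1 <- c(sin(b), 0, -cos(b)); w2 <- c(-sin(b), 0, -cos(b))
  lay <- .toyLayout()
  coords <- list()
  thCenter <- list(TH4 = c(-6, 2, 0), TH5 = c(-6, -2, 0),
                   TH10 = c(6, 2, 0), TH11 = c(6, -2, 0))
  thDir <- list(TH4 = v4, TH5 = v5, TH10 = v10, TH11 = v11)
  for (k in 1:12) {
    nm <- paste0("TH", k)
    if (nm %in% names(thCenter))
      coords[[nm]] <- .rodCentered(thCenter[[nm]], thDir[[nm]], lay[[nm]]$n)
    else {
      ang <- k * 30 * pi / 180
      coords[[nm]] <- .rodCentered(c(12 * cos(ang), 12 * sin(ang), 0),
                                   c(0, 0, 1), lay[[nm]]$n)
    }
  }
  icdFoot <- list(ICD1 = "TH4", ICD2 = "TH5", ICD3 = "TH10", ICD4 = "TH11")
  icdDir <- list(ICD1 = w1, ICD2 = w1, ICD3 = w2, ICD4 = w2)
  for (nm in names(icdFoot)) {
    foot <- thCenter[[icdFoot[[nm]]]] - 15 * thDir[[icdFoot[[nm]]]]
    coords[[nm]] <- .rodCa(foot, icdDir[[nm]], lay[[nm]]$n)
  }
  yhat <- c(0, 1, 0)
  coords$CH1 <- .rodCentered(c(-ext / 2, 3, -18), yhat, lay$CH1$n)
  coords$CH2 <- .rodCentered(c(-ext / 2, -3, -18), yhat, lay$CH2$n)
  coords$CH3 <- .rodCentered(c(ext / 2, 3, -18), yhat, lay$CH3$n)
  coords$CH4 <- .rodCentered(c(ext / 2, -3, -18), yhat, lay$CH4$n)
  coords$WAH1 <- .rodCentered(c(-18, 5, -35), yhat, lay$WAH1$n)
  coords$WAH2 <- .rodCentered(c(18, 5, -35), yhat, lay$WAH2$n)
  coords$SIG1 <- .rodCentered(c(-10, -5, -38), yhat, lay$SIG1$n)
  coords$SIG2 <- .rodCentered(c(10, -5, -38), yhat, lay$SIG2$n)
  coords$S6_1 <- .rodCentered(c(-14, 0, -28), yhat, lay$S6_1$n)
  coords$S6_2 <- .rodCentered(c(14, 0, -28), yhat, lay$S6_2$n)
  coords$S9_1 <- .rodCa(c(-int / 2, 0, -45), c(1, 0, 0), lay$S9_1$n, 3.4)
  coords$S9_2 <- .rodCa(c(int / 2, 0, -45), c(-1, 0, 0), lay$S9_2$n, 3.4)

  regionNames <- names(lay)
  xyz <- do.call(rbind, coords[regionNames])
  if (params$jitter > 0) {
    set.seed(params$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = params$jitter),
                        nrow(xyz), 3L)
  }
  Rt <- rotationAboutAxis(c(1, 0, 0), tilt)
  xyz <- xyz %*% t(Rt)

  resno <- unlist(lapply(regionNames, function(nm)
    lay[[nm]]$start + seq_len(lay[[nm]]$n) - 1L))
  atoms <- data.frame(type = "ATOM", chain = "A", resno = resno, insert = "",
                      resid = "ALA", elety = "CA", stringsAsFactors = FALSE)
  dum <- .dumGrid(c(0, 0, 0), c(0, 0, 1), 30)
  atoms <- rbind(atoms,
                 data.frame(type = "HETATM", chain = "M",
                            resno = 9000L + seq_len(nrow(dum)), insert = "",
                            resid = "DUM", elety = "DUM",
                            stringsAsFactors = FALSE))
  structure <- proteinStructure("toy-transporter", atoms, rbind(xyz, dum))

  ann <- regionAnnotation(data.frame(
    region = regionNames, chain = "A",
    start = vapply(regionNames, function(nm) lay[[nm]]$start, integer(1)),
    end = vapply(regionNames, function(nm) lay[[nm]]$start + lay[[nm]]$n - 1L,
                 integer(1))))
  membrane <- membraneModel(c(0, 0, 0), c(0, 0, 1), 30)

  cog <- function(nm) colMeans(coords[[nm]])
  pairCog <- function(n1, n2) colMeans(rbind(coords[[n1]], coords[[n2]]))
  truth <- list(
    thx_angle = thx, thv_angle = thv, icv_angle = icv, icx_angle = icv,
    nbdx_int_length = int, nbdx_ext_length = ext, tilt = tilt,
    wah_length = .norm3(cog("WAH1") - cog("WAH2")),
    s6_length = .norm3(cog("S6_1") - cog("S6_2")),
    wah1_sig2_length = .norm3(cog("WAH1") - cog("SIG2")),
    wah2_sig1_length = .norm3(cog("WAH2") - cog("SIG1")),
    nbdv1_span = .norm3(coords$S9_1[1, ] - cog("CH1")),
    class_label = rownames(conformationPrototypes())[
      which.min((thx - conformationPrototypes()$thx)^2 +
                  (icv - conformationPrototypes()$icv)^2)]
  )
  list(structure = structure, annotation = ann, membrane = membrane, truth = truth)
}

#' Synthetic closing trajectory of the toy transporter
#'
#' Linearly interpolates toy-transporter parameters over frames (emulating
#' e.g. NBD closure in an MD trajectory) and stacks the frames as a
#' multi-model structure.
#'
#' @param startParams,endParams lists from [toyTransporterParams()].
#' @param nFrames number of frames (>= 2).
#' @return list with `frames` (multi-model [ProteinStructure-class]),
#'   `annotation`, `membrane`, and `truth` (data.frame, one row per frame
#'   with the ground-truth numeric metrics).
#' @export
makeClosingTrajectory <- function(startParams, endParams, nFrames) {
  if (nFrames < 2L) stop("a trajectory needs at least 2 frames")
  fields <- c("thxAngle", "icvAngle", "nbdIntDistance", "nbdExtDistance", "tilt")
  frames <- vector("list", nFrames)
  truthRows <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    f <- (i - 1) / (nFrames - 1)
    p <- startParams
    for (fl in fields) p[[fl]] <- (1 - f) * startParams[[fl]] + f * endParams[[fl]]
    toy <- makeToyTransporter(p)
    frames[[i]] <- toy
    tr <- toy$truth[vapply(toy$truth, is.numeric, logical(1))]
    truthRows[[i]] <- data.frame(frame = i, as.data.frame(tr))
  }
  first <- frames[[1]]$structure
  coords <- lapply(frames, function(t) t$structure@coords[[1]])
  traj <- proteinStructure("toy-closing-trajectory", first@atoms, coords)
  list(frames = traj, annotation = frames[[1]]$annotation,
       membrane = frames[[1]]$membrane,
       truth = do.call(rbind, truthRows))
}
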