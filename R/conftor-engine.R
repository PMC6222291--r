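## Conftors: directed segments between anchor points (single Calpha or COG
## of Calpha sets) that characterize the relative orientation of the
## transmembrane, intracellular and nucleotide-binding domains of ABC
## Type I exporters. Angles and lengths between conftors are rigid-body
## invariant, so no prior superposition is needed for classification.

#' Construct an AnchorSpec
#'
#' @param kind one of `single_ca`, `cog_of_residues`, `cog_of_helix_ends`.
#' @param regions character vector of region names.
#' @param end which end of each region: `intracellular`, `extracellular`,
#'   `whole`, or the sequence ends `first` / `last`. Recycled.
#' @param window residues averaged at a helix end (COG when > 1). Recycled.
#' @return an [AnchorSpec-class].
#' @export
anchorSpec <- function(kind, regions, end = "whole", window = 1L) {
  t <- data.frame(region = regions,
                  end = rep_len(end, length(regions)),
                  window = as.integer(rep_len(window, length(regions))),
                  stringsAsFactors = FALSE)
  new("AnchorSpec", kind = kind, targets = t)
}

#' Construct a ConftorSpec
#'
#' @param name conftor name.
#' @param origin,tip [AnchorSpec-class] objects.
#' @param orientation orientation class: `"TH"` (membrane conftors, forced
#'   to point intracellular to extracellular), `"IC"` (intracellular, the
#'   reverse) or `"free"`.
#' @return a [ConftorSpec-class].
#' @export
conftorSpec <- function(name, origin, tip, orientation = "free") {
  new("ConftorSpec", name = name, origin = origin, tip = tip,
      orientation = orientation)
}

#' The standard ABC Type I exporter conftor set
#'
#' Returns the built-in registry:
#' \describe{
#'   \item{THV1/THV2}{single-helix TM vectors along TH4 and TH10, pointing
#'     from the intracellular to the extracellular helix end.}
#'   \item{THX1/THX2}{cross-over TM conftors whose ends are the COG of the
#'     Calpha at the ends of the helix pairs TH4+TH5 and TH10+TH11 (these
#'     helices cross from one TMD to the opposite NBD).}
#'   \item{ICV1/ICV2, ICX1/ICX2}{intracellular continuations of the same
#'     helices (ICD1/ICD3 and the pairs ICD1+ICD2 / ICD3+ICD4), pointing
#'     away from the membrane.}
#'   \item{NBDV1/NBDV2, NBDX1/NBDX2}{from the COG of the coupling helices
#'     contacting each NBD (CH1 / CH1+CH2 and CH3 / CH3+CH4) to the first
#'     residue of strand S9, the last NBD strand.}
#'   \item{S6, WAH}{between the opposite S6 strands and the opposite
#'     Walker-A helices (COG to COG).}
#'   \item{WAH1_SIG2 / WAH2_SIG1}{Walker-A helix COG to the opposite
#'     signature-motif COG, one per composite ATP site.}
#' }
#' Which concrete residue ranges (and hence which coupling helices feed
#' which NBD conftor) apply to a given structure is carried entirely by its
#' annotation table; the registry only names regions.
#'
#' @return named list of [ConftorSpec-class] objects.
#' @export
builtinConftorRegistry <- function() {
  one <- function(r, e) anchorSpec("single_ca", r, e)
  cogr <- function(r) anchorSpec("cog_of_residues", r)
  ends <- function(r, e, w = 1L) anchorSpec("cog_of_helix_ends", r, e, w)
  specs <- list(
    conftorSpec("THV1", one("TH4", "intracellular"), one("TH4", "extracellular"), "TH"),
    conftorSpec("THV2", one("TH10", "intracellular"), one("TH10", "extracellular"), "TH"),
    conftorSpec("THX1", ends(c("TH4", "TH5"), "intracellular"),
                ends(c("TH4", "TH5"), "extracellular"), "TH"),
    conftorSpec("THX2", ends(c("TH10", "TH11"), "intracellular"),
                ends(c("TH10", "TH11"), "extracellular"), "TH"),
    conftorSpec("ICV1", one("ICD1", "extracellular"), one("ICD1", "intracellular"), "IC"),
    conftorSpec("ICV2", one("ICD3", "extracellular"), one("ICD3", "intracellular"), "IC"),
    conftorSpec("ICX1", ends(c("ICD1", "ICD2"), "extracellular"),
                ends(c("ICD1", "ICD2"), "intracellular"), "IC"),
    conftorSpec("ICX2", ends(c("ICD3", "ICD4"), "extracellular"),
                ends(c("ICD3", "ICD4"), "intracellular"), "IC"),
    conftorSpec("NBDV1", cogr("CH1"), one("S9_1", "first")),
    conftorSpec("NBDV2", cogr("CH3"), one("S9_2", "first")),
    conftorSpec("NBDX1", cogr(c("CH1", "CH2")), one("S9_1", "first")),
    conftorSpec("NBDX2", cogr(c("CH3", "CH4")), one("S9_2", "first")),
    conftorSpec("S6", cogr("S6_1"), cogr("S6_2")),
    conftorSpec("WAH", cogr("WAH1"), cogr("WAH2")),
    conftorSpec("WAH1_SIG2", cogr("WAH1"), cogr("SIG2")),
    conftorSpec("WAH2_SIG1", cogr("WAH2"), cogr("SIG1"))
  )
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  specs
}

## which terminal residue of a region is on which membrane side
.regionEndResidues <- function(structure, annotation, region, model = 1L) {
  e <- regions(annotation)
  row <- e[e$region == region, , drop = FALSE]
  if (nrow(row) == 0L) stop("region '", region, "' is not annotated")
  list(chain = row$chain[1], start = row$start[1], end = row$end[1])
}

## intracellular side reference: projection onto the membrane normal when a
## membrane is available; otherwise proximity to the NBD-region COG
.intracellularScore <- function(structure, annotation, point, membrane, model = 1L) {
  if (!is.null(membrane)) {
    sum((point - membraneCenter(membrane)) * membraneNormal(membrane))
  } else {
    nbdRegions <- intersect(regions(annotation)$region,
                            c("CH1", "CH2", "CH3", "CH4", "WAH1", "WAH2",
                              "SIG1", "SIG2", "S6_1", "S6_2", "S9_1", "S9_2"))
    if (length(nbdRegions) == 0L)
      stop("cannot orient helix ends: no membrane model and no NBD regions annotated")
    cog <- centerOfGeometry(regionCa(structure, annotation, nbdRegions, model))
    ## distance to the NBD COG: lower score = intracellular, matching the
    ## membrane-projection branch
    sqrt(sum((point - cog)^2))
  }
}

## anchor point of one region end
.endAnchor <- function(structure, annotation, region, end, window, membrane, model = 1L) {
  r <- .regionEndResidues(structure, annotation, region, model)
  window <- max(1L, as.integer(window))
  anchorAt <- function(resno, inwardStep) {
    if (window == 1L)
      .caSingle(structure, r$chain, resno, model, inwardStep)
    else {
      span <- if (inwardStep > 0L) resno:min(resno + window - 1L, r$end)
              else resno:max(resno - window + 1L, r$start)
      colMeans(.caRange(structure, r$chain, min(span), max(span), model))
    }
  }
  if (end == "first") return(anchorAt(r$start, 1L))
  if (end == "last") return(anchorAt(r$end, -1L))
  if (end == "whole")
    return(colMeans(.caRange(structure, r$chain, r$start, r$end, model)))
  pStart <- .caSingle(structure, r$chain, r$start, model, 1L)
  pEnd <- .caSingle(structure, r$chain, r$end, model, -1L)
  sStart <- .intracellularScore(structure, annotation, pStart, membrane, model)
  sEnd <- .intracellularScore(structure, annotation, pEnd, membrane, model)
  startIsIntra <- sStart < sEnd
  wantStart <- (end == "intracellular") == startIsIntra
  if (wantStart) anchorAt(r$start, 1L) else anchorAt(r$end, -1L)
}

#' Resolve an AnchorSpec to a point
#'
#' @param structure a [ProteinStructure-class].
#' @param annotation a [RegionAnnotation-class].
#' @param anchor an [AnchorSpec-class].
#' @param membrane optional [MembraneModel-class], used to decide which
#'   helix end is intracellular.
#' @param model model index.
#' @return numeric(3) anchor point.
#' @export
resolveAnchor <- function(structure, annotation, anchor, membrane = NULL, model = 1L) {
  t <- anchor@targets
  if (anchor@kind == "cog_of_residues") {
    pts <- do.call(rbind, lapply(seq_len(nrow(t)), function(i) {
      r <- .regionEndResidues(structure, annotation, t$region[i], model)
      .caRange(structure, r$chain, r$start, r$end, model)
    }))
    return(colMeans(pts))
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(t)), function(i)
    .endAnchor(structure, annotation, t$region[i], t$end[i], t$window[i],
               membrane, model)))
  if (anchor@kind == "single_ca") pts[1, ] else colMeans(pts)
}

#' Compute a conftor on a structure
#'
#' Anchor points are resolved per the spec; membrane-region ("TH" class)
#' conftors are checked against the membrane normal and flipped (with a
#' warning) if they point extracellular to intracellular; "IC" class
#' conftors are held to the opposite convention.
#'
#' @param structure a [ProteinStructure-class].
#' @param annotation a [RegionAnnotation-class].
#' @param spec a [ConftorSpec-class] or the name of a registry conftor.
#' @param membrane optional [MembraneModel-class].
#' @param registry conftor registry (named list of specs).
#' @param model model index.
#' @return a [Conftor-class].
#' @export
computeConftor <- function(structure, annotation, spec, membrane = NULL,
                           registry = builtinConftorRegistry(), model = 1L) {
  if (is.character(spec)) {
    if (!spec %in% names(registry)) stop("unknown conftor: ", spec)
    spec <- registry[[spec]]
  }
  validateAnnotation(annotation, spec)
  origin <- resolveAnchor(structure, annotation, spec@origin, membrane, model)
  tip <- resolveAnchor(structure, annotation, spec@tip, membrane, model)
  v <- tip - origin
  if (.norm3(v) <= 0.5)
    stop("conftor ", spec@name, ": origin and tip coincide (separation ",
         sprintf("%.3f", .norm3(v)), " A)")
  if (!is.null(membrane) && spec@orientation %in% c("TH", "IC")) {
    proj <- sum(v * membraneNormal(membrane))
    wantPositive <- spec@orientation == "TH"
    if ((proj < 0) == wantPositive) {
      warning("conftor ", spec@name, " violated the ",
              if (wantPositive) "intracellular->extracellular"
              else "membrane->cytosol",
              " convention; origin and tip swapped", call. = FALSE)
      tmp <- origin; origin <- tip; tip <- tmp
    }
  }
  new("Conftor", name = spec@name, origin = origin, tip = tip)
}

#' Angle between two conftors, in degrees
#'
#' Rotation- and translation-invariant; no superposition is required.
#'
#' @inheritParams computeConftor
#' @param nameA,nameB registry names (or [ConftorSpec-class] objects).
#' @return degrees in [0, 180].
#' @export
conftorAngle <- function(structure, annotation, nameA, nameB, membrane = NULL,
                         registry = builtinConftorRegistry(), model = 1L) {
  a <- computeConftor(structure, annotation, nameA, membrane, registry, model)
  b <- computeConftor(structure, annotation, nameB, membrane, registry, model)
  vectorAngle(conftorVector(a), conftorVector(b))
}

#' Conftor length metrics, in Angstrom
#'
#' For `endpointPair = "span"`, the length of the named conftor. For
#' `"ext"` / `"int"`, `name` is a conftor pair prefix (e.g. `"NBDX"`):
#' `ext` is the distance between the two origin anchors (for NBDX, the
#' coupling-helix COGs at the NBD/TMD interface) and `int` the distance
#' between the two tip anchors (for NBDX, the first residues of S9 at the
#' NBD bottom).
#'
#' @inheritParams computeConftor
#' @param name conftor name (`span`) or pair prefix (`ext`/`int`).
#' @param endpointPair one of `span`, `ext`, `int`.
#' @return length in Angstrom.
#' @export
conftorLength <- function(structure, annotation, name,
                          endpointPair = c("span", "ext", "int"),
                          membrane = NULL, registry = builtinConftorRegistry(),
                          model = 1L) {
  endpointPair <- match.arg(endpointPair)
  if (endpointPair == "span") {
    cf <- computeConftor(structure, annotation, name, membrane, registry, model)
    return(.norm3(conftorVector(cf)))
  }
  n1 <- paste0(name, "1"); n2 <- paste0(name, "2")
  c1 <- computeConftor(structure, annotation, n1, membrane, registry, model)
  c2 <- computeConftor(structure, annotation, n2, membrane, registry, model)
  if (endpointPair == "ext") .norm3(c1@origin - c2@origin)
  else .norm3(c1@tip - c2@tip)
}

#' Conformation-class prototype angles
#'
#' Class-average angle signatures (degrees): the THX1/THX2 angle separates
#' bottom-open inward-facing (46), bottom-closed top-closed i.e. occluded
#' (26) and the two remaining classes (39 and 35); the ICV1/ICV2 angle
#' separates inward-facing (43 and 38), outward-facing (60) and occluded
#' (53). The THV1/THV2 angle averages 23 for occluded versus 36-40 for all
#' other classes and is carried for reference.
#'
#' @return data.frame with rownames = class labels and columns `thx`,
#'   `icv`, `thv`.
#' @export
conformationPrototypes <- function() {
  data.frame(
    thx = c(46, 39, 35, 26),
    icv = c(43, 38, 60, 53),
    thv = c(38, 38, 38, 23),
    row.names = c("bottom_open_inward_facing", "bottom_closed_inward_facing",
                  "bottom_closed_outward_facing", "occluded")
  )
}

#' Classify a conformation from conftor metrics
#'
#' Nearest-prototype assignment in (THX angle, ICV angle) space against the
#' class-average signatures of [conformationPrototypes()]. The ambiguity
#' flag is set when the two best classes are closer than `margin` in total
#' distance. When the two best classes are the two inward-facing ones and
#' an NBDX ext length is supplied, the NBD separation breaks the tie
#' (separation above `extOpenThreshold` = bottom-open).
#'
#' @param metrics named list/vector with `thx_angle` and `icv_angle`
#'   (degrees), optionally `nbdx_ext_length` (Angstrom).
#' @param margin ambiguity margin in degrees (default 5).
#' @param extOpenThreshold NBDX ext length above which an ambiguous
#'   inward-facing structure is called bottom-open (Angstrom).
#' @return a [ConformationClass-class].
#' @export
classifyConformation <- function(metrics, margin = 5, extOpenThreshold = 40) {
  metrics <- as.list(metrics)
  if (is.null(metrics$thx_angle) || is.null(metrics$icv_angle))
    stop("classification requires both thx_angle and icv_angle")
  p <- conformationPrototypes()
  d <- sqrt((metrics$thx_angle - p$thx)^2 + (metrics$icv_angle - p$icv)^2)
  names(d) <- rownames(p)
  ord <- order(d)
  label <- rownames(p)[ord[1]]
  ambiguous <- (d[ord[2]] - d[ord[1]]) < margin
  inward <- c("bottom_open_inward_facing", "bottom_closed_inward_facing")
  if (ambiguous && setequal(rownames(p)[ord[1:2]], inward) &&
      !is.null(metrics$nbdx_ext_length)) {
    label <- if (metrics$nbdx_ext_length > extOpenThreshold) inward[1] else inward[2]
    ambiguous <- FALSE
  }
  new("ConformationClass", label = label, distances = d,
      ambiguityFlag = isTRUE(ambiguous))
}

## ---- metric mini-language -------------------------------------------------
## "angle:THX1:THX2"          inter-conftor angle (degrees)
## "length:WAH1_SIG2"         conftor span length (Angstrom)
## "length:NBDX:ext|int"      pair distance metrics (Angstrom)

.parseMetricSpec <- function(metric) {
  parts <- strsplit(metric, ":", fixed = TRUE)[[1]]
  if (parts[1] == "angle" && length(parts) == 3L)
    return(list(kind = "angle", a = parts[2], b = parts[3]))
  if (parts[1] == "length" && length(parts) == 2L)
    return(list(kind = "length", name = parts[2], pair = "span"))
  if (parts[1] == "length" && length(parts) == 3L &&
      parts[3] %in% c("ext", "int", "span"))
    return(list(kind = "length", name = parts[2], pair = parts[3]))
  stop("unparseable metric '", metric,
       "' (use angle:<A>:<B> or length:<name>[:ext|int|span])")
}

#' Evaluate conftor metrics on one model of a structure
#'
#' @inheritParams computeConftor
#' @param metrics character vector in the metric mini-language:
#'   `angle:<A>:<B>`, `length:<name>` (span) or `length:<prefix>:ext|int`.
#' @return named numeric vector, one value per metric.
#' @export
computeMetrics <- function(structure, annotation, metrics, membrane = NULL,
                           registry = builtinConftorRegistry(), model = 1L) {
  vapply(metrics, function(m) {
    s <- .parseMetricSpec(m)
    if (s$kind == "angle")
      conftorAngle(structure, annotation, s$a, s$b, membrane, registry, model)
    else
      conftorLength(structure, annotation, s$name, s$pair, membrane, registry, model)
  }, numeric(1))
}

#' Conftor metrics over a coordinate-frame series
#'
#' Evaluates each requested metric on every model of a multi-model
#' structure (e.g. an MD trajectory written as multi-model PDB), preserving
#' frame order.
#'
#' @param frames a [ProteinStructure-class] with one model per frame.
#' @param annotation a [RegionAnnotation-class] valid for every frame.
#' @param metrics character vector in the metric mini-language (see
#'   [computeMetrics()]).
#' @param membrane optional [MembraneModel-class].
#' @param registry conftor registry.
#' @return named list of [MetricSeries-class], one per metric.
#' @export
trajectoryMetrics <- function(frames, annotation, metrics, membrane = NULL,
                              registry = builtinConftorRegistry()) {
  nf <- nModels(frames)
  out <- lapply(metrics, function(m) {
    vals <- vapply(seq_len(nf), function(i) {
      tryCatch(
        computeMetrics(frames, annotation, m, membrane, registry, model = i),
        error = function(e) stop("frame ", i, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
    }, numeric(1))
    new("MetricSeries", metricName = m, frameIndices = seq_len(nf),
        values = as.numeric(vals))
  })
  names(out) <- metrics
  out
}
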