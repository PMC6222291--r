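#' @rdname ProteinStructure-class
#' @param x,object a `ProteinStructure`.
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname ProteinStructure-class
#' @param model integer model index.
#' @export
setGeneric("modelCoords", function(x, model = 1L) standardGeneric("modelCoords"))

#' @rdname RegionAnnotation-class
#' @param x a `RegionAnnotation`.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname MembraneModel-class
#' @param x a `MembraneModel`.
#' @export
setGeneric("membraneCenter", function(x) standardGeneric("membraneCenter"))

#' @rdname MembraneModel-class
#' @export
setGeneric("membraneNormal", function(x) standardGeneric("membraneNormal"))

#' @rdname MembraneModel-class
#' @export
setGeneric("membraneThickness", function(x) standardGeneric("membraneThickness"))

#' @rdname Conftor-class
#' @param x a `Conftor`.
#' @export
setGeneric("conftorVector", function(x) standardGeneric("conftorVector"))

#' @rdname Conftor-class
#' @export
setGeneric("conftorName", function(x) standardGeneric("conftorName"))

setMethod("identifier", "ProteinStructure", function(x) x@identifier)
setMethod("nModels", "ProteinStructure", function(x) length(x@coords))
setMethod("atomData", "ProteinStructure", function(x) x@atoms)
setMethod("modelCoords", "ProteinStructure", function(x, model = 1L) {
  model <- as.integer(model)
  if (model < 1L || model > length(x@coords))
    stop("model ", model, " not present in structure '", x@identifier,
         "' (", length(x@coords), " model(s))")
  x@coords[[model]]
})

setMethod("regions", "RegionAnnotation", function(x) x@entries)

setMethod("membraneCenter", "MembraneModel", function(x) x@center)
setMethod("membraneNormal", "MembraneModel", function(x) x@normal)
setMethod("membraneThickness", "MembraneModel", function(x) x@thickness)

setMethod("conftorVector", "Conftor", function(x) x@tip - x@origin)
setMethod("conftorName", "Conftor", function(x) x@name)

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure '", object@identifier, "': ", nrow(object@atoms),
      " atoms, ", length(object@coords), " model(s), ",
      length(unique(object@atoms$chain)), " chain(s)\n", sep = "")
  ndum <- sum(object@atoms$resid == "DUM")
  if (ndum) cat("  includes ", ndum, " membrane DUMMY atoms\n", sep = "")
})

setMethod("show", "RegionAnnotation", function(object) {
  e <- object@entries
  cat("RegionAnnotation: ", nrow(e), " region(s) on chain(s) ",
      paste(unique(e$chain), collapse = ", "), "\n", sep = "")
  if (nrow(e)) print(utils::head(e, 12), row.names = FALSE)
  if (nrow(e) > 12) cat("  ...\n")
})

setMethod("show", "MembraneModel", function(object) {
  cat(sprintf("MembraneModel: center (%.2f, %.2f, %.2f) A, normal (%.3f, %.3f, %.3f)",
              object@center[1], object@center[2], object@center[3],
              object@normal[1], object@normal[2], object@normal[3]))
  if (!is.na(object@thickness)) cat(sprintf(", thickness %.1f A", object@thickness))
  cat("\n")
})

setMethod("show", "Conftor", function(object) {
  v <- object@tip - object@origin
  cat(sprintf("Conftor %s: (%.2f, %.2f, %.2f) -> (%.2f, %.2f, %.2f), length %.2f A\n",
              object@name, object@origin[1], object@origin[2], object@origin[3],
              object@tip[1], object@tip[2], object@tip[3], sqrt(sum(v^2))))
})

setMethod("show", "ConformationClass", function(object) {
  cat("ConformationClass:", object@label,
      if (object@ambiguityFlag) "(ambiguous)" else "", "\n")
  cat("  prototype distances:",
      paste(sprintf("%s=%.1f", names(object@distances), object@distances),
            collapse = ", "), "\n")
})

setMethod("show", "HelixGeometry", function(object) {
  cat(sprintf(paste0("HelixGeometry %s: %d windows, max bending %.1f deg, ",
                     "twist %.1f deg/res, rise %.2f A/res\n"),
              object@helixName, nrow(object@windowAxes), object@maxBending,
              object@twistPerResidue, object@risePerResidue))
})

setMethod("show", "MetricSeries", function(object) {
  cat(sprintf("MetricSeries %s: %d frames, range [%.3f, %.3f]\n",
              object@metricName, length(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: fine (%g, %g, %g) A, dimension %d^3, membrane %.1f A, scan +/- %g A\n",
              object@fine[1], object@fine[2], object@fine[3], object@dimension,
              object@membraneThickness, object@zScanRange))
})

#' Coerce a MetricSeries to a data.frame
#'
#' @param x a `MetricSeries`.
#' @param ... ignored.
#' @return data.frame with columns `metric`, `frame`, `value`.
#' @export
as.data.frame.MetricSeries <- function(x, ...) {
  data.frame(metric = x@metricName, frame = x@frameIndices, value = x@values)
}
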