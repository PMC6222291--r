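## End-to-end report generation: the programmatic surface behind the
## command-line tool. All tables are sorted on (structure_id, metric/name)
## so identical inputs give byte-identical reports.

#' Run configuration for report generation
#'
#' @param structurePaths character vector of structure files (PDB/mmCIF).
#' @param annotationPath region-annotation TSV.
#' @param membraneSource `"opm-file"` (DUM atoms in `membranePath` or the
#'   structure itself), `"leaflet-file"` (bead PDB in `membranePath`) or
#'   `"none"`.
#' @param membranePath optional membrane file.
#' @param referencePath optional reference structure for projection frames.
#' @param metrics character vector in the metric mini-language (see
#'   [computeMetrics()]); default the standard classification set.
#' @param outputDir output directory (created if absent).
#' @param seed integer seed recorded in the config.
#' @return validated config (list).
#' @export
runConfig <- function(structurePaths, annotationPath,
                      membraneSource = c("opm-file", "leaflet-file", "none"),
                      membranePath = NULL, referencePath = NULL,
                      metrics = c("angle:THX1:THX2", "angle:ICV1:ICV2",
                                  "angle:THV1:THV2", "length:NBDX:ext",
                                  "length:NBDX:int"),
                      outputDir = ".", seed = 1L) {
  membraneSource <- match.arg(membraneSource)
  for (p in c(structurePaths, annotationPath, membranePath, referencePath))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  list(structurePaths = structurePaths, annotationPath = annotationPath,
       membraneSource = membraneSource, membranePath = membranePath,
       referencePath = referencePath, metrics = metrics,
       outputDir = outputDir, seed = as.integer(seed))
}

.resolveMembrane <- function(config, structure) {
  switch(config$membraneSource,
    "none" = NULL,
    "opm-file" = {
      src <- if (is.null(config$membranePath)) structure
             else readStructure(config$membranePath)
      parseOpmMembrane(src)
    },
    "leaflet-file" = {
      beads <- leafletBeads(readStructure(config$membranePath))
      membraneFromLeaflets(beads$upper, beads$lower)
    })
}

#' Generate conftor, metric and classification reports
#'
#' For every structure in the config: computes all registry conftors that
#' the annotation supports (`conftors.tsv`), evaluates the requested
#' metrics (`metrics.tsv`), and classifies the conformation when the THX
#' and ICV angles are among the metrics (`classification.json`). With
#' `projections = TRUE`, TM-helix end projections are written
#' (`projections.tsv`). Multi-model structures additionally produce
#' `trajectory.tsv` with per-frame metric series.
#'
#' @param config list from [runConfig()].
#' @param registry conftor registry.
#' @param projections also write helix-end projections.
#' @return invisibly, named list of output file paths.
#' @export
runReport <- function(config, registry = builtinConftorRegistry(),
                      projections = FALSE) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  annotation <- loadAnnotation(config$annotationPath)
  have <- regions(annotation)$region
  conftorRows <- list(); metricRows <- list(); classOut <- list()
  projRows <- list(); trajRows <- list()
  for (path in config$structurePaths) {
    s <- readStructure(path)
    mem <- .resolveMembrane(config, s)
    usable <- Filter(function(sp)
      all(c(sp@origin@targets$region, sp@tip@targets$region) %in% have),
      registry)
    for (sp in usable) {
      cf <- computeConftor(s, annotation, sp, mem, registry)
      v <- conftorVector(cf)
      conftorRows[[length(conftorRows) + 1L]] <- data.frame(
        structure_id = identifier(s), conftor = conftorName(cf),
        origin_x = cf@origin[1], origin_y = cf@origin[2], origin_z = cf@origin[3],
        tip_x = cf@tip[1], tip_y = cf@tip[2], tip_z = cf@tip[3],
        length_A = .norm3(v), stringsAsFactors = FALSE)
    }
    vals <- computeMetrics(s, annotation, config$metrics, mem, registry)
    if (length(vals)) metricRows[[length(metricRows) + 1L]] <- data.frame(
      structure_id = identifier(s), metric = names(vals), value = unname(vals),
      units = ifelse(startsWith(names(vals), "angle"), "degrees", "Angstrom"),
      stringsAsFactors = FALSE)
    thx <- vals["angle:THX1:THX2"]; icvv <- vals["angle:ICV1:ICV2"]
    if (!is.na(thx) && !is.na(icvv)) {
      cl <- classifyConformation(list(
        thx_angle = unname(thx), icv_angle = unname(icvv),
        nbdx_ext_length = if (!is.na(vals["length:NBDX:ext"]))
          unname(vals["length:NBDX:ext"]) else NULL))
      classOut[[identifier(s)]] <- list(
        label = cl@label, distances = as.list(cl@distances),
        ambiguity_flag = cl@ambiguityFlag)
    }
    if (projections && !is.null(mem)) {
      pr <- projectHelixEnds(s, annotation, mem)
      pr <- data.frame(structure_id = identifier(s), pr)
      projRows[[length(projRows) + 1L]] <- pr
    }
    if (nModels(s) > 1L) {
      series <- trajectoryMetrics(s, annotation, config$metrics, mem, registry)
      df <- do.call(rbind, lapply(series, as.data.frame))
      trajRows[[length(trajRows) + 1L]] <-
        data.frame(structure_id = identifier(s), df)
    }
  }
  out <- list()
  writeSorted <- function(rows, file, keys) {
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df <- df[do.call(order, df[keys]), , drop = FALSE]
    p <- file.path(config$outputDir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  out$conftors <- writeSorted(conftorRows, "conftors.tsv",
                              c("structure_id", "conftor"))
  out$metrics <- writeSorted(metricRows, "metrics.tsv",
                             c("structure_id", "metric"))
  if (length(classOut)) {
    out$classification <- file.path(config$outputDir, "classification.json")
    jsonlite::write_json(classOut[order(names(classOut))], out$classification,
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(projRows))
    out$projections <- writeSorted(projRows, "projections.tsv",
                                   c("structure_id", "helix", "side"))
  if (length(trajRows))
    out$trajectory <- writeSorted(trajRows, "trajectory.tsv",
                                  c("structure_id", "metric", "frame"))
  invisible(out)
}
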