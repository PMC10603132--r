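#' @include AllClasses.R
NULL

#' Panel accessors
#'
#' @param x a [FirePanel-class] (or, where noted, another fireCausal object).
#' @return `panelValues`: the numeric weeks x variables matrix;
#'   `variableGroups`: named character vector of group tags;
#'   `targetVariable`: identifier of the variable tagged `"target"` (or
#'   `NA`); `nWeeks`: number of weeks; `weekOfYear`: integer labels;
#'   `panelMetadata`: the metadata list.
#' @name panel-accessors
#' @aliases panelValues variableGroups targetVariable nWeeks weekOfYear
#'   panelMetadata
NULL

#' @rdname panel-accessors
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))
#' @rdname panel-accessors
#' @export
setGeneric("variableGroups", function(x) standardGeneric("variableGroups"))
#' @rdname panel-accessors
#' @export
setGeneric("targetVariable", function(x) standardGeneric("targetVariable"))
#' @rdname panel-accessors
#' @export
setGeneric("nWeeks", function(x) standardGeneric("nWeeks"))
#' @rdname panel-accessors
#' @export
setGeneric("weekOfYear", function(x) standardGeneric("weekOfYear"))
#' @rdname panel-accessors
#' @export
setGeneric("panelMetadata", function(x) standardGeneric("panelMetadata"))

#' @rdname panel-accessors
setMethod("panelValues", "FirePanel", function(x) x@values)
#' @rdname panel-accessors
setMethod("variableGroups", "FirePanel",
          function(x) setNames(x@groups, colnames(x@values)))
#' @rdname panel-accessors
setMethod("targetVariable", "FirePanel", function(x) {
  i <- which(x@groups == "target")
  if (length(i)) colnames(x@values)[i[1]] else NA_character_
})
#' @rdname panel-accessors
setMethod("nWeeks", "FirePanel", function(x) nrow(x@values))
#' @rdname panel-accessors
setMethod("weekOfYear", "FirePanel", function(x) x@weekOfYear)
#' @rdname panel-accessors
setMethod("panelMetadata", "FirePanel", function(x) x@metadata)

#' Graph accessors
#'
#' @param x a [CausalGraph-class].
#' @param var variable identifier (for `parentSet`).
#' @return `causalLinks`: data.frame of retained links; `parentSet`: the
#'   selection-stage parent table of one variable; `auditMatrices`: list of
#'   the full `rho`, `p`, and effective-sample-size arrays;
#'   `graphConfig`: the [PCMCIConfig-class] used.
#' @name graph-accessors
#' @aliases causalLinks parentSet auditMatrices graphConfig
NULL

#' @rdname graph-accessors
#' @export
setGeneric("causalLinks", function(x) standardGeneric("causalLinks"))
#' @rdname graph-accessors
#' @export
setGeneric("parentSet", function(x, var) standardGeneric("parentSet"))
#' @rdname graph-accessors
#' @export
setGeneric("auditMatrices", function(x) standardGeneric("auditMatrices"))
#' @rdname graph-accessors
#' @export
setGeneric("graphConfig", function(x) standardGeneric("graphConfig"))

#' @rdname graph-accessors
setMethod("causalLinks", "CausalGraph", function(x) x@links)
#' @rdname graph-accessors
setMethod("parentSet", "CausalGraph", function(x, var) x@parents[[var]])
#' @rdname graph-accessors
setMethod("auditMatrices", "CausalGraph",
          function(x) list(rho = x@rho, p = x@p, ess = x@ess))
#' @rdname graph-accessors
setMethod("graphConfig", "CausalGraph", function(x) x@config)

#' Scene accessors
#'
#' @param x a [ClassifiedScene-class].
#' @return `scenePixels`: the pixel classification data.frame;
#'   `sceneGroundTruth`: planted per-ecoregion dominance table.
#' @name scene-accessors
#' @aliases scenePixels sceneGroundTruth
NULL

#' @rdname scene-accessors
#' @export
setGeneric("scenePixels", function(x) standardGeneric("scenePixels"))
#' @rdname scene-accessors
#' @export
setGeneric("sceneGroundTruth", function(x) standardGeneric("sceneGroundTruth"))

#' @rdname scene-accessors
setMethod("scenePixels", "ClassifiedScene", function(x) x@pixels)
#' @rdname scene-accessors
setMethod("sceneGroundTruth", "ClassifiedScene", function(x) x@groundTruth)

setMethod("show", "FirePanel", function(object) {
  cat(sprintf("FirePanel: %d weeks x %d variables\n",
              nrow(object@values), ncol(object@values)))
  g <- table(factor(object@groups, levels = .GROUPS))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(g), g), collapse = ", ")))
  cat(sprintf("  target: %s\n", targetVariable(object)))
  if (anyNA(object@values))
    cat(sprintf("  missing entries: %d\n", sum(is.na(object@values))))
  steps <- object@metadata$pipeline
  if (!is.null(steps))
    cat(sprintf("  preprocessing: %s\n", paste(steps, collapse = " -> ")))
})

setMethod("show", "PCMCIConfig", function(object) {
  cat(sprintf(
    "PCMCIConfig: alpha=%g, pcAlpha=%g, tau in [%d, %d], qMax=%d, maxConds=%d%s\n",
    object@alpha, object@pcAlpha, object@tauMin, object@tauMax,
    object@qMax, object@maxConds, if (object@bh) ", BH post-filter" else ""))
})

setMethod("show", "CausalGraph", function(object) {
  cat(sprintf("CausalGraph: %d variables, lags %d..%d, %d retained link(s)\n",
              length(object@variables), object@config@tauMin,
              object@config@tauMax, nrow(object@links)))
  if (nrow(object@links)) {
    k <- head(object@links, 5)
    for (i in seq_len(nrow(k)))
      cat(sprintf("  %s -> %s @ lag %d: rho=%+.3f p=%.2g\n",
                  k$source[i], k$target[i], k$lag[i], k$rho[i], k$pvalue[i]))
    if (nrow(object@links) > 5)
      cat(sprintf("  ... and %d more\n", nrow(object@links) - 5L))
  }
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec: %d variables, %d weeks, %d planted link(s), seed %d\n",
              length(object@variables), object@nWeeks, nrow(object@links),
              object@seed))
  cat(sprintf("  spectral radius: %.3f\n", spectralRadius(object)))
})

setMethod("show", "ClassifiedScene", function(object) {
  d <- dim(object@data)
  cat(sprintf("ClassifiedScene: %d weeks x %d pixels x %d variables, %d ecoregion(s)\n",
              d[1], d[2], d[3], length(unique(object@pixels$ecoregion))))
})

setMethod("show", "DominanceRecord", function(object) {
  cat(sprintf("DominanceRecord [%s]: dominant %s", object@ecoregion,
              object@dominantGroup))
  if (object@dominantGroup != "none")
    cat(sprintf(" (%s @ lag %g, score %.3f, %d link(s))",
                object@dominantPrecursor, object@dominantLag,
                object@score, nrow(object@links)))
  cat("\n")
})

setMethod("show", "ClimatologyModel", function(object) {
  cat(sprintf("ClimatologyModel: trend %.4g + %.4g/week; %d/52 weekly means\n",
              object@intercept, object@slope,
              sum(!is.na(object@weeklyMeans))))
})
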