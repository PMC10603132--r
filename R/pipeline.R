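#' @include attribution.R
#' @include ecoregion.R
#' @include scene.R
#' @include preprocess.R
NULL

#' Write a panel as tidy and wide CSV
#'
#' @param panel a [FirePanel-class].
#' @param path output path without extension; writes `<path>_wide.csv`
#'   (week, week_of_year, one column per variable) and `<path>_tidy.csv`
#'   (week_index, variable, value).
#' @return Invisibly, the two paths written.
#' @export
writePanelCSV <- function(panel, path) {
  v <- panelValues(panel)
  wide <- data.frame(week = seq_len(nrow(v)),
                     week_of_year = weekOfYear(panel), v,
                     check.names = FALSE)
  tidy <- data.frame(week_index = rep(seq_len(nrow(v)), ncol(v)),
                     variable = rep(colnames(v), each = nrow(v)),
                     value = as.vector(v))
  pw <- paste0(path, "_wide.csv"); pt <- paste0(path, "_tidy.csv")
  write.csv(wide, pw, row.names = FALSE)
  write.csv(tidy, pt, row.names = FALSE)
  invisible(c(pw, pt))
}

#' Write a causal graph as a JSON edge list and CSV
#'
#' @param graph a [CausalGraph-class].
#' @param path output path without extension; writes `<path>.json` (edge
#'   list of source/target/lag/rho/pvalue) and `<path>.csv`.
#' @return Invisibly, the paths written.
#' @export
writeGraph <- function(graph, path) {
  lk <- causalLinks(graph)
  pj <- paste0(path, ".json"); pc <- paste0(path, ".csv")
  jsonlite::write_json(lk, pj, digits = NA, dataframe = "rows")
  write.csv(lk, pc, row.names = FALSE)
  invisible(c(pj, pc))
}

#' Serialize fitted climatology models as JSON for audit
#'
#' @param climatology named list of [ClimatologyModel-class] (one per
#'   variable), as returned by [preprocessPanel()].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeClimatologyJSON <- function(climatology, path) {
  out <- lapply(climatology, function(cm)
    list(intercept = cm@intercept, slope = cm@slope,
         weeklyMeans = cm@weeklyMeans))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full synthetic-mode attribution pipeline
#'
#' Orchestrates the fixed stage order on a simulated scene: (1) mask
#' low-confidence burned-area pixel-weeks, (2) collapse pixels to one raw
#' weekly panel per ecoregion (burned-area sum, area-weighted precursor
#' means), (3) preprocess each panel (log transform of burned area, linear
#' detrend, seasonal-anomaly), (4) two-stage causal discovery per
#' ecoregion, (5) dominance attribution, sign fractions, group lags,
#' covariate-binned profiles and zone/type dominance fractions from the
#' pixel classification. Reruns with the same scene and configuration are
#' bit-reproducible (the discovery stage holds no internal randomness).
#'
#' @param scene a [ClassifiedScene-class] (see [simulateScene()]).
#' @param config a [PCMCIConfig-class].
#' @param maskThreshold percent confidence mask for burned area (default
#'   70).
#' @param weighting `"cosine"` or `"uniform"` precursor pixel weights.
#' @param nBins bins of the covariate dominance profiles.
#' @param profileCovariates variables to profile dominance against (their
#'   per-pixel time means), any subset of the panel variables.
#' @param grouping precursor-to-group mapping (`NULL`: from the scene's
#'   own group tags).
#' @param outDir optional output directory; when given, writes
#'   `dominance.csv`, `sign_fractions.csv`, per-ecoregion
#'   `graph_<id>.json/.csv`, `profile_<var>.csv`, `zone_dominance.csv`,
#'   `type_dominance.csv`, and `manifest.json`.
#' @return List: `panels` (preprocessed anomaly panels), `graphs`,
#'   `records`, `dominance` (table), `signs`, `pixelTable`, `profiles`,
#'   `zoneType`, `manifest`.
#' @export
runFullPipeline <- function(scene, config = pcmciConfig(),
                            maskThreshold = 70,
                            weighting = c("cosine", "uniform"),
                            nBins = 200L,
                            profileCovariates = c("Tmax", "VPD", "EVI"),
                            grouping = NULL,
                            outDir = NULL) {
  weighting <- match.arg(weighting)
  t0 <- proc.time()[["elapsed"]]

  pix0 <- scenePixels(scene)
  present <- unique(pix0[, c("climate", "vegetation")])
  present <- present[order(present$climate, present$vegetation), ]
  keys <- data.frame(climate = present$climate,
                     vegetation = present$vegetation,
                     id = paste(present$climate, present$vegetation,
                                sep = ":"), stringsAsFactors = FALSE)
  raw <- aggregateToEcoregion(scene, keys = keys, weighting = weighting,
                              maskThreshold = maskThreshold)

  panels <- list(); graphs <- list(); records <- list()
  warningsLog <- character(0)
  for (eco in names(raw)) {
    pp <- preprocessPanel(raw[[eco]])
    panels[[eco]] <- pp$panel
    g <- tryCatch(runPCMCI(pp$panel, config),
                  error = function(e)
                    stop(sprintf("discovery failed in ecoregion %s: %s",
                                 eco, conditionMessage(e)), call. = FALSE))
    graphs[[eco]] <- g
    md <- panelMetadata(raw[[eco]])
    records[[eco]] <- attributeDominance(
      g, grouping, ecoregion = eco, area = md$totalArea)
  }

  dom <- dominanceTable(records)
  signs <- signFractions(records)

  # pixel table: each pixel inherits its ecoregion's attribution
  pix <- scenePixels(scene)
  m <- match(pix$ecoregion, dom$ecoregion)
  pixelTable <- data.frame(
    pix,
    dominantGroup = dom$dominantGroup[m],
    dominantLag = dom$dominantLag[m],
    lag = ifelse(dom$dominantGroup[m] == "top-down", dom$topDownLag[m],
                 ifelse(dom$dominantGroup[m] == "bottom-up",
                        dom$bottomUpLag[m], NA_real_)),
    stringsAsFactors = FALSE)
  pixelTable$dominantGroup[is.na(pixelTable$dominantGroup)] <- "none"

  profiles <- list()
  vars <- dimnames(scene@data)[[3]]
  for (cv in intersect(profileCovariates, vars)) {
    k <- match(cv, vars)
    pm <- colMeans(scene@data[, , k], na.rm = TRUE)
    pd <- data.frame(value = pm,
                     dominantGroup = pixelTable$dominantGroup,
                     lag = pixelTable$lag, area = pixelTable$area)
    profiles[[cv]] <- binnedDominanceProfile(pd, nBins = nBins)
  }
  pd <- data.frame(value = pixelTable$lat,
                   dominantGroup = pixelTable$dominantGroup,
                   lag = pixelTable$lag, area = pixelTable$area)
  profiles[["latitude"]] <- binnedDominanceProfile(pd, nBins = nBins)

  zt <- zoneTypeDominance(pixelTable)

  manifest <- list(
    package = "fireCausal",
    version = as.character(utils::packageVersion("fireCausal")),
    config = list(alpha = config@alpha, pcAlpha = config@pcAlpha,
                  tauMin = config@tauMin, tauMax = config@tauMax,
                  qMax = config@qMax, maxConds = config@maxConds,
                  bh = config@bh, maskThreshold = maskThreshold,
                  weighting = weighting, nBins = nBins),
    sceneSeed = scene@metadata$seed,
    nEcoregions = length(graphs),
    nLinksRetained = sum(vapply(graphs,
                                function(g) nrow(causalLinks(g)),
                                numeric(1))),
    nMaskedBA = if (length(raw))
      panelMetadata(raw[[1]])$nMaskedBA else 0L,
    elapsedSeconds = proc.time()[["elapsed"]] - t0)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(dom, file.path(outDir, "dominance.csv"), row.names = FALSE)
    write.csv(signs, file.path(outDir, "sign_fractions.csv"),
              row.names = FALSE)
    for (eco in names(graphs))
      writeGraph(graphs[[eco]],
                 file.path(outDir, paste0("graph_", gsub(":", "_", eco))))
    for (cv in names(profiles))
      write.csv(profiles[[cv]],
                file.path(outDir, paste0("profile_", cv, ".csv")),
                row.names = FALSE)
    write.csv(zt$climate, file.path(outDir, "zone_dominance.csv"),
              row.names = FALSE)
    write.csv(zt$vegetation, file.path(outDir, "type_dominance.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(panels = panels, graphs = graphs, records = records,
       dominance = dom, signs = signs, pixelTable = pixelTable,
       profiles = profiles, zoneType = zt, manifest = manifest)
}
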