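#' @include simulate.R
NULL

#' The ten standard wildfire precursors and their grouping
#'
#' Top-down (weather) precursors: maximum air temperature (Tmax), vapor
#' pressure deficit (VPD), potential evaporation (ET0), wind speed (Wind),
#' aridity anomaly index (AAI). Bottom-up (fuel) precursors: fraction of
#' photosynthetically active radiation (FPAR), gross primary production
#' (GPP), NDVI, EVI, soil water deficit index (SWDI).
#'
#' @return Named character vector mapping precursor identifier to group.
#' @examples
#' defaultGrouping()[["SWDI"]]
#' @export
defaultGrouping <- function() {
  c(Tmax = "top-down", VPD = "top-down", ET0 = "top-down",
    Wind = "top-down", AAI = "top-down",
    FPAR = "bottom-up", GPP = "bottom-up", NDVI = "bottom-up",
    EVI = "bottom-up", SWDI = "bottom-up")
}

#' The eight vegetation-type codes of the stratification
#'
#' sparse vegetation, grassland, cropland, shrubland, tree cover broad-leaf
#' evergreen (TBE), tree cover broad-leaf deciduous (TBD), tree cover
#' needle-leaf evergreen (TNE), tree cover needle-leaf deciduous (TND).
#'
#' @return Named integer vector of codes.
#' @export
vegetationClasses <- function() {
  setNames(1:8, c("sparse", "grassland", "cropland", "shrubland",
                  "TBE", "TBD", "TNE", "TND"))
}

#' Construct a gridded scene specification
#'
#' @param climate,vegetation integer matrices (same shape) of per-pixel
#'   classification codes.
#' @param scenarios named list of [ScenarioSpec-class] keyed by ecoregion
#'   identifier `"<climate>:<vegetation>"`, one per ecoregion present.
#' @param pixelNoiseSd sd of independent per-pixel noise (anomaly scale).
#' @param confidenceLevels,confidenceProbs discrete per-pixel-week
#'   burned-area confidence distribution on `[0, 100]`.
#' @param lat row-center latitudes in degrees (default equally spaced in
#'   (-60, 60), a 0.25-degree grid centered on the fire-prone latitudes).
#' @param seed integer.
#' @return A validated [SceneSpec-class].
#' @seealso [simulateScene()]
#' @export
sceneSpec <- function(climate, vegetation, scenarios,
                      pixelNoiseSd = 0.2,
                      confidenceLevels = c(30, 50, 80, 95),
                      confidenceProbs = c(0.05, 0.05, 0.5, 0.4),
                      lat = NULL, seed = 1L) {
  climate <- as.matrix(climate); vegetation <- as.matrix(vegetation)
  if (is.null(lat))
    lat <- seq(-60 + 0.125, 60 - 0.125, length.out = nrow(climate))
  new("SceneSpec", climate = climate, vegetation = vegetation,
      lat = as.numeric(lat), scenarios = scenarios,
      pixelNoiseSd = as.numeric(pixelNoiseSd),
      confidenceLevels = as.numeric(confidenceLevels),
      confidenceProbs = as.numeric(confidenceProbs),
      seed = as.integer(seed))
}

#' Simulate a classified gridded scene
#'
#' Every ecoregion (climate x vegetation stratum) on the grid is driven by
#' its own [ScenarioSpec-class] signal; each member pixel observes that
#' signal plus independent Gaussian pixel noise, and the target layer is
#' rendered per pixel through the ecoregion's zero-inflated skew marginal
#' (so pixel-level burned area has exact zeros). A percent-confidence layer
#' is drawn per pixel-week from the declared discrete distribution.
#'
#' The planted ground truth records, for every ecoregion, the group owning
#' the planted link of largest absolute standardized effect into the target
#' (|coefficient| x latent sd of the source / latent sd of the target).
#'
#' @param scene a [SceneSpec-class].
#' @return A [ClassifiedScene-class].
#' @examples
#' cl <- matrix(1L, 2, 2); vg <- matrix(1L, 2, 2)
#' sc <- scenarioSpec(c("X", "BA"), c("top-down", "target"),
#'                    links = plantedLink("X", "BA", 1, 0.6),
#'                    nWeeks = 300, seed = 3)
#' scn <- simulateScene(sceneSpec(cl, vg, list("1:1" = sc),
#'                                pixelNoiseSd = 0))
#' sceneGroundTruth(scn)
#' @export
simulateScene <- function(scene) {
  validObject(scene)
  nr <- nrow(scene@climate); nc <- ncol(scene@climate)
  pix <- data.frame(pixel = seq_len(nr * nc),
                    row = rep(seq_len(nr), times = nc),
                    col = rep(seq_len(nc), each = nr))
  pix$lat <- scene@lat[pix$row]
  pix$area <- cos(pix$lat * pi / 180)
  pix$climate <- as.integer(scene@climate)[pix$pixel]
  pix$vegetation <- as.integer(scene@vegetation)[pix$pixel]
  pix$ecoregion <- paste(pix$climate, pix$vegetation, sep = ":")

  ecoIds <- unique(pix$ecoregion)
  sc1 <- scene@scenarios[[ecoIds[1]]]
  T <- sc1@nWeeks
  vars <- sc1@variables
  groups <- sc1@groups
  nPix <- nrow(pix)
  dat <- array(NA_real_, c(T, nPix, length(vars)),
               dimnames = list(NULL, NULL, vars))
  tgt <- which(groups == "target")

  gt <- vector("list", length(ecoIds))
  plantedLinks <- vector("list", length(ecoIds))
  names(plantedLinks) <- ecoIds

  for (ei in seq_along(ecoIds)) {
    eco <- ecoIds[ei]
    sp <- scene@scenarios[[eco]]
    if (!identical(sp@variables, vars))
      stop("all ecoregion scenarios must share the variable set")
    panel <- simulatePanel(sp)
    md <- panelMetadata(panel)
    sig <- panelValues(panel)
    members <- which(pix$ecoregion == eco)
    for (j in seq_along(members)) {
      px <- members[j]
      set.seed(((scene@seed + 7919L * px) %% 2147483629L) + 1L)
      noise <- if (scene@pixelNoiseSd > 0)
        matrix(rnorm(T * length(vars), sd = scene@pixelNoiseSd),
               T, length(vars))
      else matrix(0, T, length(vars))
      v <- sig + noise
      if (sp@baSkewTransform) {
        # pixel burned area: latent ecoregion series + pixel noise pushed
        # through the same zero-inflated marginal
        v[, tgt] <- .baTransform(md$latentTarget + noise[, tgt],
                                 md$baThreshold)
      }
      dat[, px, ] <- v
    }
    gt[[ei]] <- .plantedDominance(sp, md, eco)
    plantedLinks[[eco]] <- md$groundTruth
  }

  set.seed(((scene@seed + 104729L) %% 2147483629L) + 1L)
  conf <- matrix(sample(scene@confidenceLevels, T * nPix, replace = TRUE,
                        prob = scene@confidenceProbs), T, nPix)

  new("ClassifiedScene", data = dat, confidence = conf, pixels = pix,
      groups = groups, weekOfYear = rep_len(1:52, T),
      groundTruth = do.call(rbind, gt),
      metadata = list(seed = scene@seed, plantedLinks = plantedLinks,
                      pixelNoiseSd = scene@pixelNoiseSd))
}

# Ground-truth dominance of one ecoregion: among planted links into the
# target, the largest absolute standardized effect wins.
.plantedDominance <- function(sp, md, eco) {
  tgtVar <- sp@variables[sp@groups == "target"]
  lk <- sp@links[sp@links$target == tgtVar & sp@links$source != tgtVar, ,
                 drop = FALSE]
  if (!nrow(lk))
    return(data.frame(ecoregion = eco, dominantGroup = "none",
                      dominantPrecursor = NA_character_,
                      dominantLag = NA_integer_, stringsAsFactors = FALSE))
  eff <- abs(lk$coefficient) * md$latentSd[lk$source] /
    md$latentSd[tgtVar]
  i <- which.max(eff)
  grp <- sp@groups[match(lk$source[i], sp@variables)]
  data.frame(ecoregion = eco, dominantGroup = grp,
             dominantPrecursor = lk$source[i],
             dominantLag = as.integer(lk$lag[i]), stringsAsFactors = FALSE)
}

#' Build the standard multi-ecoregion synthetic study scene
#'
#' The package's reference experiment: `nEcoregions` strata laid out on a
#' grid (`pixelsPerEcoregion` pixels each, climate codes cycling over rows
#' of eight vegetation classes), each driven by an 18-year weekly panel (936
#' weeks) of the ten standard precursors plus burned area. Per ecoregion one
#' dominant link into burned area is planted (|coefficient| 0.65): a
#' positive top-down link at a short lag (0-4 weeks) or a negative
#' bottom-up link at a seasonal-to-interannual lag (20-70 weeks), following
#' the sign and lag structure typical of flammability- versus fuel-limited
#' fire regimes. A weaker (0.25) secondary link from the opposite group
#' makes dominance a genuine contest. Precursors carry AR(1) = 0.5
#' autocorrelation, a seasonal cycle, and a weak trend; burned area is
#' rendered zero-inflated (35% zero weeks) and right-skewed.
#'
#' @param nEcoregions number of strata (default 50).
#' @param pixelsPerEcoregion pixels per stratum (default 4).
#' @param nWeeks panel length (default 936 = 18 years x 52 weeks).
#' @param seed integer master seed; per-ecoregion scenario seeds are derived
#'   deterministically from it.
#' @param topDownShare probability that an ecoregion's planted dominant
#'   group is top-down (default 0.5).
#' @return A [SceneSpec-class] ready for [simulateScene()].
#' @export
syntheticStudy <- function(nEcoregions = 50L, pixelsPerEcoregion = 4L,
                           nWeeks = 936L, seed = 1L, topDownShare = 0.5) {
  grouping <- defaultGrouping()
  vars <- c("BA", names(grouping))
  groups <- c("target", unname(grouping))
  td <- names(grouping)[grouping == "top-down"]
  bu <- names(grouping)[grouping == "bottom-up"]

  climate <- matrix(rep(((seq_len(nEcoregions) - 1L) %/% 8L) + 1L,
                        each = pixelsPerEcoregion),
                    nrow = pixelsPerEcoregion)
  veg <- matrix(rep(((seq_len(nEcoregions) - 1L) %% 8L) + 1L,
                    each = pixelsPerEcoregion),
                nrow = pixelsPerEcoregion)

  set.seed(seed)
  scenarios <- list()
  for (e in seq_len(nEcoregions)) {
    eco <- paste(climate[1, e], veg[1, e], sep = ":")
    domTop <- runif(1) < topDownShare
    if (domTop) {
      domVar <- sample(td, 1)
      domLag <- sample(0:4, 1)
      domCoef <- 0.65
      secVar <- sample(bu, 1)
      secLag <- sample(20:70, 1)
      secCoef <- -0.25
    } else {
      domVar <- sample(bu, 1)
      domLag <- sample(20:70, 1)
      domCoef <- -0.65
      secVar <- sample(td, 1)
      secLag <- sample(0:4, 1)
      secCoef <- 0.25
    }
    links <- rbind(plantedLink(domVar, "BA", domLag, domCoef),
                   plantedLink(secVar, "BA", secLag, secCoef))
    scenarios[[eco]] <- scenarioSpec(
      vars, groups, links = links,
      noiseSd = 1, seasonalAmplitude = c(1, rep(2, 10)),
      trendSlope = 0.001, nWeeks = nWeeks,
      seed = ((seed + 7717L * e) %% 2147483629L) + 1L,
      arCoef = c(0, rep(0.5, 10)),
      baZeroInflation = 0.35, baSkewTransform = TRUE)
  }
  sceneSpec(climate, veg, scenarios, seed = seed)
}
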