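#' @include fireCausal-package.R
NULL

.GROUPS <- c("top-down", "bottom-up", "target")

#' FirePanel: a multivariate weekly anomaly panel
#'
#' The unit of causal discovery: a T x N matrix of weekly values, one column
#' per variable, each variable tagged as a `top-down` precursor, `bottom-up`
#' precursor, or the `target` (burned area). Missing entries are `NA` and are
#' never silently dropped; conditional-independence tests use listwise
#' deletion over the union of lagged index sets.
#'
#' @slot values numeric matrix, weeks in rows, variables in columns
#'   (colnames are the variable identifiers).
#' @slot groups character vector parallel to the columns; each entry one of
#'   `"top-down"`, `"bottom-up"`, `"target"`.
#' @slot weekOfYear integer vector of length `nrow(values)` with entries in
#'   1..52 (fixed 52-week years; week 52 absorbs days 365/366).
#' @slot metadata list of provenance: planted ground truth, preprocessing
#'   steps applied, ecoregion membership, etc.
#'
#' @seealso [firePanel()], [simulatePanel()], [preprocessPanel()]
#' @export
setClass("FirePanel",
  representation(values = "matrix", groups = "character",
                 weekOfYear = "integer", metadata = "list"))

setValidity("FirePanel", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (is.null(colnames(v))) return("'values' must have column names")
  if (anyDuplicated(colnames(v))) return("duplicate variable identifiers")
  if (length(object@groups) != ncol(v))
    return("'groups' must have one entry per variable")
  if (!all(object@groups %in% .GROUPS))
    return(sprintf("groups must be in {%s}", paste(.GROUPS, collapse = ", ")))
  if (length(object@weekOfYear) != nrow(v))
    return("'weekOfYear' must have one entry per week")
  w <- object@weekOfYear
  if (any(!is.na(w) & (w < 1L | w > 52L)))
    return("'weekOfYear' entries must lie in 1..52")
  TRUE
})

#' Construct a FirePanel
#'
#' @param values numeric matrix (weeks x variables) with column names.
#' @param groups character vector of group tags (`"top-down"`,
#'   `"bottom-up"`, `"target"`), recycled from a named vector if it carries
#'   names matching the columns.
#' @param weekOfYear integer vector of week-of-year labels (1..52); default
#'   cycles 1..52 from the first row.
#' @param metadata list of free-form provenance.
#' @return A [FirePanel-class] object.
#' @examples
#' m <- cbind(BA = rnorm(120), Tmax = rnorm(120))
#' p <- firePanel(m, groups = c("target", "top-down"))
#' nWeeks(p)
#' @export
firePanel <- function(values, groups, weekOfYear = NULL, metadata = list()) {
  values <- as.matrix(values)
  if (!is.null(names(groups)) && !is.null(colnames(values)))
    groups <- unname(groups[colnames(values)])
  if (is.null(weekOfYear))
    weekOfYear <- rep_len(1:52, nrow(values))
  new("FirePanel", values = values, groups = as.character(groups),
      weekOfYear = as.integer(weekOfYear), metadata = metadata)
}

#' PCMCIConfig: settings for the two-stage causal discovery
#'
#' Defaults follow the study configuration: significance level 0.05 and a
#' maximum time lag of 156 weeks (three years at weekly cadence). `pcAlpha`
#' defaults to `alpha` (one level for both stages); `qMax` bounds the
#' conditioning-set growth of the selection stage and `maxConds` caps the
#' number of conditioners contributed by each side of an MCI test.
#'
#' @slot alpha significance level for link retention (MCI stage).
#' @slot tauMax maximum time lag in weeks.
#' @slot tauMin minimum time lag (0 admits contemporaneous links, which are
#'   oriented precursor -> target a priori).
#' @slot pcAlpha significance level of the PC selection stage.
#' @slot qMax maximum conditioning dimension in the PC stage.
#' @slot maxConds cap on conditioners per side in the MCI stage.
#' @slot bh logical; apply a Benjamini-Hochberg post-filter over the MCI
#'   p-matrix before retention (off by default).
#' @seealso [pcmciConfig()], [runPCMCI()]
#' @export
setClass("PCMCIConfig",
  representation(alpha = "numeric", tauMax = "integer", tauMin = "integer",
                 pcAlpha = "numeric", qMax = "integer", maxConds = "integer",
                 bh = "logical"))

setValidity("PCMCIConfig", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (object@pcAlpha <= 0 || object@pcAlpha >= 1)
    return("pcAlpha must be in (0,1)")
  if (object@tauMin < 0L) return("tauMin must be >= 0")
  if (object@tauMax < object@tauMin) return("tauMax must be >= tauMin")
  if (object@qMax < 0L) return("qMax must be >= 0")
  if (object@maxConds < 1L) return("maxConds must be >= 1")
  TRUE
})

#' @rdname PCMCIConfig-class
#' @param alpha,tauMax,tauMin,pcAlpha,qMax,maxConds,bh see the class slots.
#' @return A [PCMCIConfig-class] object.
#' @examples
#' pcmciConfig(alpha = 0.05, tauMax = 10)
#' @export
pcmciConfig <- function(alpha = 0.05, tauMax = 156L, tauMin = 0L,
                        pcAlpha = alpha, qMax = 3L, maxConds = 5L,
                        bh = FALSE) {
  new("PCMCIConfig", alpha = alpha, tauMax = as.integer(tauMax),
      tauMin = as.integer(tauMin), pcAlpha = pcAlpha,
      qMax = as.integer(qMax), maxConds = as.integer(maxConds), bh = bh)
}

#' CausalGraph: the result of two-stage causal discovery
#'
#' Holds the retained lagged links (p <= alpha after the MCI stage), the
#' per-variable parent sets chosen by the selection stage, the configuration
#' used, and the full rho / p-value / effective-sample-size audit arrays over
#' every tested (source, target, lag) triple.
#'
#' @slot links data.frame with columns `source`, `target`, `lag`, `rho`,
#'   `pvalue`, sorted by decreasing `|rho|`.
#' @slot parents named list (one entry per variable) of data.frames with
#'   columns `var`, `lag`, `absmin` (the selection-stage strength).
#' @slot config the [PCMCIConfig-class] used.
#' @slot rho,p,ess numeric arrays `source x target x lag` (lag index runs
#'   `tauMin..tauMax`); untested entries are `NA`.
#' @slot variables,groups the panel's variable identifiers and group tags.
#' @export
setClass("CausalGraph",
  representation(links = "data.frame", parents = "list",
                 config = "PCMCIConfig", rho = "array", p = "array",
                 ess = "array", variables = "character",
                 groups = "character"))

setValidity("CausalGraph", function(object) {
  lk <- object@links
  need <- c("source", "target", "lag", "rho", "pvalue")
  if (!all(need %in% names(lk))) return("links lacks required columns")
  taus <- as.integer(dimnames(object@rho)[[3]])
  if (nrow(lk)) {
    for (i in seq_len(nrow(lk))) {
      a <- object@rho[lk$source[i], lk$target[i], match(lk$lag[i], taus)]
      if (!isTRUE(all.equal(unname(a), lk$rho[i], tolerance = 1e-12)))
        return("retained link rho disagrees with audit matrix")
    }
  }
  TRUE
})

#' ClimatologyModel: fitted trend and seasonal cycle of one weekly series
#'
#' @slot intercept,slope ordinary-least-squares linear trend (value units,
#'   units per week) fitted on the week index.
#' @slot weeklyMeans numeric of length 52: the multi-year mean of the
#'   detrended series at each week of year (`NA` for weeks never observed).
#' @export
setClass("ClimatologyModel",
  representation(intercept = "numeric", slope = "numeric",
                 weeklyMeans = "numeric"))

#' @rdname ClimatologyModel-class
#' @param intercept,slope,weeklyMeans see slots.
#' @return A [ClimatologyModel-class].
#' @export
climatologyModel <- function(intercept = NA_real_, slope = NA_real_,
                             weeklyMeans = rep(NA_real_, 52)) {
  new("ClimatologyModel", intercept = intercept, slope = slope,
      weeklyMeans = weeklyMeans)
}

#' ScenarioSpec: declarative description of one synthetic panel experiment
#'
#' Defines the planted lagged linear system and its dressing: per-variable
#' noise, seasonal cycle, linear trend, and the burned-area marginal
#' (optional expm1-type skew transform with quantile zero inflation). The
#' validity method rejects unstable systems (companion-matrix spectral
#' radius >= 1) and overly short runs.
#'
#' @slot variables ordered variable identifiers.
#' @slot groups parallel group tags (exactly one `"target"`).
#' @slot links data.frame of planted links: `source`, `target`, `lag`
#'   (weeks, >= 0), `coefficient`.
#' @slot noiseSd,seasonalAmplitude,trendSlope per-variable numerics.
#' @slot seasonalPeriod integer weeks (default 52).
#' @slot nWeeks,seed integers.
#' @slot arCoef per-variable AR(1) self-dependence added to the planted
#'   links (0 = white noise innovations only).
#' @slot baZeroInflation probability in `[0,1]`: fraction of target weeks
#'   forced to exact zero (quantile thresholding of the latent series).
#' @slot baSkewTransform logical: apply the expm1 marginal transform to the
#'   target so that a log1p preprocessing step approximately recovers
#'   Gaussianity.
#' @seealso [scenarioSpec()], [simulatePanel()]
#' @export
setClass("ScenarioSpec",
  representation(variables = "character", groups = "character",
                 links = "data.frame", noiseSd = "numeric",
                 seasonalAmplitude = "numeric", seasonalPeriod = "integer",
                 trendSlope = "numeric", nWeeks = "integer", seed = "integer",
                 arCoef = "numeric", baZeroInflation = "numeric",
                 baSkewTransform = "logical"))

setValidity("ScenarioSpec", function(object) {
  nv <- length(object@variables)
  if (nv < 1L) return("at least one variable required")
  if (anyDuplicated(object@variables)) return("duplicate variable identifiers")
  if (length(object@groups) != nv) return("one group tag per variable required")
  if (!all(object@groups %in% .GROUPS))
    return("groups must be top-down / bottom-up / target")
  if (sum(object@groups == "target") != 1L)
    return("exactly one variable must be tagged 'target'")
  for (s in c("noiseSd", "seasonalAmplitude", "trendSlope", "arCoef"))
    if (length(slot(object, s)) != nv)
      return(sprintf("'%s' must have one entry per variable", s))
  if (any(object@noiseSd <= 0)) return("noiseSd must be > 0")
  if (any(object@seasonalAmplitude < 0))
    return("seasonalAmplitude must be >= 0")
  lk <- object@links
  if (nrow(lk)) {
    if (!all(c("source", "target", "lag", "coefficient") %in% names(lk)))
      return("links needs columns source, target, lag, coefficient")
    if (!all(lk$source %in% object@variables) ||
        !all(lk$target %in% object@variables))
      return("link endpoints must be declared variables")
    if (any(lk$lag < 0L)) return("link lags must be >= 0")
    if (any(lk$lag == 0L & lk$source == lk$target))
      return("self-link at lag 0 is not allowed")
  }
  maxLag <- max(c(0L, lk$lag, if (any(object@arCoef != 0)) 1L))
  if (object@nWeeks <= 2L * maxLag + 100L)
    return("nWeeks must exceed 2 * max planted lag + 100")
  if (object@baZeroInflation < 0 || object@baZeroInflation > 1)
    return("baZeroInflation must be in [0,1]")
  sr <- spectralRadius(object)
  if (sr >= 1)
    return(sprintf(
      "planted lagged system is unstable (spectral radius %.3f >= 1)", sr))
  TRUE
})

#' SceneSpec: declarative description of a gridded synthetic scene
#'
#' A rectangular 0.25-degree grid where every pixel carries a climate-zone
#' code and a vegetation-type code; each resulting ecoregion (climate x
#' vegetation stratum) is driven by one [ScenarioSpec-class] signal, and
#' pixels add independent noise plus a per-pixel-week burned-area confidence
#' draw from a declared discrete distribution on `[0, 100]`.
#'
#' @slot climate,vegetation integer matrices of identical shape (pixel
#'   classification codes).
#' @slot lat numeric vector of row-center latitudes (degrees), used for
#'   cosine area weights.
#' @slot scenarios named list of [ScenarioSpec-class], keyed by ecoregion
#'   identifier (`"<climate>:<vegetation>"`); every ecoregion present on the
#'   grid must have one.
#' @slot pixelNoiseSd numeric: sd of independent per-pixel noise added to
#'   the ecoregion signal (anomaly scale).
#' @slot confidenceLevels,confidenceProbs discrete confidence distribution.
#' @slot seed integer.
#' @seealso [sceneSpec()], [simulateScene()]
#' @export
setClass("SceneSpec",
  representation(climate = "matrix", vegetation = "matrix", lat = "numeric",
                 scenarios = "list", pixelNoiseSd = "numeric",
                 confidenceLevels = "numeric", confidenceProbs = "numeric",
                 seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (!all(dim(object@climate) == dim(object@vegetation)))
    return("climate and vegetation grids must share shape")
  if (anyNA(object@climate) || anyNA(object@vegetation))
    return("every pixel must carry exactly one (climate, vegetation) pair")
  if (length(object@lat) != nrow(object@climate))
    return("'lat' needs one entry per grid row")
  eco <- unique(paste(object@climate, object@vegetation, sep = ":"))
  missing <- setdiff(eco, names(object@scenarios))
  if (length(missing))
    return(sprintf("no scenario for ecoregion(s): %s",
                   paste(missing, collapse = ", ")))
  if (length(object@confidenceLevels) != length(object@confidenceProbs))
    return("confidenceLevels and confidenceProbs must align")
  if (any(object@confidenceLevels < 0 | object@confidenceLevels > 100))
    return("confidence levels must lie in [0, 100]")
  if (abs(sum(object@confidenceProbs) - 1) > 1e-9)
    return("confidenceProbs must sum to 1")
  nw <- vapply(object@scenarios, function(s) s@nWeeks, integer(1))
  if (length(unique(nw)) > 1L)
    return("all ecoregion scenarios must share nWeeks")
  TRUE
})

#' ClassifiedScene: a simulated gridded scene with ground truth
#'
#' @slot data numeric array `weeks x pixels x variables` of per-pixel weekly
#'   values (burned area already on its observed, possibly zero-inflated
#'   scale).
#' @slot confidence numeric matrix `weeks x pixels` (percent, 0..100),
#'   applying to the burned-area layer.
#' @slot pixels data.frame: `pixel`, `row`, `col`, `lat`, `area`, `climate`,
#'   `vegetation`, `ecoregion`.
#' @slot groups variable group tags (parallel to the third array dimension).
#' @slot weekOfYear integer week-of-year labels.
#' @slot groundTruth data.frame per ecoregion: planted `dominantGroup`,
#'   `dominantPrecursor`, `dominantLag`.
#' @slot metadata list (scene spec echo, planted links per ecoregion).
#' @export
setClass("ClassifiedScene",
  representation(data = "array", confidence = "matrix",
                 pixels = "data.frame", groups = "character",
                 weekOfYear = "integer", groundTruth = "data.frame",
                 metadata = "list"))

setValidity("ClassifiedScene", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("'data' must be weeks x pixels x variables")
  if (!all(dim(object@confidence) == d[1:2]))
    return("'confidence' must be weeks x pixels")
  if (nrow(object@pixels) != d[2]) return("one pixels row per pixel required")
  if (length(object@groups) != d[3]) return("one group tag per variable")
  if (length(object@weekOfYear) != d[1]) return("one weekOfYear per week")
  if (any(object@pixels$area <= 0)) return("area weights must be > 0")
  TRUE
})

#' DominanceRecord: per-ecoregion attribution result
#'
#' @slot ecoregion ecoregion identifier.
#' @slot area total area weight of the ecoregion (for area-weighted
#'   cross-ecoregion summaries).
#' @slot dominantGroup `"top-down"`, `"bottom-up"`, or `"none"` (no
#'   significant precursor link detected).
#' @slot dominantPrecursor,dominantLag identifier and lag (weeks) of the
#'   strongest precursor link; `NA` when none.
#' @slot score predictability score: sum of squared partial correlations of
#'   the precursors' strongest links.
#' @slot links collapsed per-precursor link table (`precursor`, `group`,
#'   `lag`, `rho`, `pvalue`), one row per precursor with a retained link.
#' @slot groupMeanLags named numeric: |rho|-weighted mean lag per group
#'   (`NA` when the group has no links).
#' @export
setClass("DominanceRecord",
  representation(ecoregion = "character", area = "numeric",
                 dominantGroup = "character",
                 dominantPrecursor = "character", dominantLag = "numeric",
                 score = "numeric", links = "data.frame",
                 groupMeanLags = "numeric"))

setValidity("DominanceRecord", function(object) {
  if ((object@dominantGroup == "none") != (nrow(object@links) == 0L))
    return("dominantGroup is 'none' iff the link table is empty")
  if (nrow(object@links) &&
      max(abs(object@links$rho)) >
        abs(object@links$rho[match(object@dominantPrecursor,
                                   object@links$precursor)]) + 1e-12)
    return("dominant precursor must carry the maximal |rho|")
  if (object@score < 0) return("score must be >= 0")
  TRUE
})
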