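#' @include AllClasses.R
NULL

#' Mask low-confidence entries
#'
#' Entries whose percent confidence is strictly below the threshold are set
#' to missing; all others pass through unchanged. The default threshold of
#' 70 reproduces the standard burned-area quality-control rule ("lower
#' than 70%" is strict, so a confidence of exactly 70 is kept).
#'
#' @param values numeric vector/matrix/array.
#' @param confidence numeric object of the same shape, percent in `[0, 100]`.
#' @param threshold percent threshold in `[0, 100]` (default 70).
#' @return List with `values` (masked copy) and `nMasked` (count of newly
#'   masked entries).
#' @examples
#' maskLowConfidence(c(1, 2, 3), c(69, 70, 100))$nMasked
#' @export
maskLowConfidence <- function(values, confidence, threshold = 70) {
  if (!identical(dim(values), dim(confidence)) ||
      length(values) != length(confidence))
    stop("values and confidence must share shape")
  if (threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]")
  bad <- !is.na(confidence) & confidence < threshold & !is.na(values)
  values[bad] <- NA_real_
  list(values = values, nMasked = sum(bad))
}

# Fixed 52-week calendar fold: week w covers days of year 7(w-1)+1 .. 7w,
# and week 52 additionally absorbs days 365 and 366.
.weekOfDate <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  pmin.int((doy - 1L) %/% 7L + 1L, 52L)
}

#' Aggregate a daily series to weekly values
#'
#' Uses a fixed 52-week year: week w covers days-of-year `7(w-1)+1 .. 7w`,
#' with week 52 absorbing days 365/366, so `week_of_year` is well defined
#' across years. Means drop missing days (an empty week is missing); sums
#' propagate missingness, so encode observed zero burned area as `0`, not
#' `NA`.
#'
#' @param values numeric daily values.
#' @param dates `Date` vector parallel to `values`.
#' @param method `"mean"` (precursors) or `"sum"` (burned area).
#' @return data.frame with `year`, `week_of_year`, `value`.
#' @examples
#' d <- seq(as.Date("2003-01-01"), by = "day", length.out = 14)
#' aggregateToWeekly(rep(2, 14), d, "mean")$value
#' @export
aggregateToWeekly <- function(values, dates, method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(dates))
  dates <- as.Date(dates)
  year <- as.integer(format(dates, "%Y"))
  week <- .weekOfDate(dates)
  key <- paste(year, formatC(week, width = 2, flag = "0"), sep = "-")
  split_v <- split(values, key)
  agg <- vapply(split_v, function(v) {
    if (method == "mean") {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else mean(v)
    } else {
      sum(v)  # NA propagates: an unobserved day poisons the weekly sum
    }
  }, numeric(1))
  uk <- names(agg)
  data.frame(year = as.integer(substr(uk, 1, 4)),
             week_of_year = as.integer(substr(uk, 6, 7)),
             value = unname(agg))
}

#' Log-transform burned area
#'
#' `value -> log(value + offset)` with the default offset of 1 (i.e.
#' `log1p`), which is defined at the exact-zero weeks of burned-area
#' series, zero-preserving, and monotone. Pulls the right-skewed weekly
#' burned-area marginal toward Gaussianity before causal testing.
#'
#' @param values non-negative numeric.
#' @param offset positive offset (default 1).
#' @return Transformed numeric of the same shape.
#' @examples
#' logTransformBA(c(0, exp(1) - 1))
#' @export
logTransformBA <- function(values, offset = 1) {
  if (any(values < 0, na.rm = TRUE))
    stop("burned area must be non-negative")
  if (offset <= 0) stop("offset must be > 0")
  if (offset == 1) log1p(values) else log(values + offset)
}

#' Remove a linear trend by ordinary least squares
#'
#' Regresses the series on its week index (with intercept) over the
#' non-missing entries and returns the residuals; missing entries stay
#' missing. For a complete series the residual mean is 0 to machine
#' precision.
#'
#' @param values numeric weekly series.
#' @param minObs minimum number of non-missing entries (default 104, two
#'   complete years).
#' @return List with `values` (residuals), `intercept`, `slope` (units per
#'   week).
#' @examples
#' detrendLinear(3 + 0.01 * (1:200))$slope
#' @export
detrendLinear <- function(values, minObs = 104L) {
  ok <- !is.na(values)
  if (sum(ok) < minObs)
    stop(sprintf("detrending needs >= %d non-missing entries", minObs))
  t <- seq_along(values)
  fit <- lm.fit(cbind(1, t[ok]), values[ok])
  out <- rep(NA_real_, length(values))
  out[ok] <- fit$residuals
  list(values = out, intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]))
}

#' Remove the seasonal cycle by week-of-year anomaly
#'
#' `anomaly(t) = value(t) - mean over all years of value at
#' week_of_year(t)`: the multi-year week-of-year climatological mean is
#' subtracted, with no smoothing window. Every week-of-year's anomaly mean
#' is 0 to machine precision for complete series, and the operation is
#' idempotent.
#'
#' @param values numeric weekly series.
#' @param weekOfYear integer labels in 1..52 parallel to `values`.
#' @return List with `values` (anomalies; missing stays missing) and
#'   `weeklyMeans` (length-52 numeric, `NA` for weeks of year absent from
#'   the series).
#' @examples
#' x <- rep(sin(2 * pi * (1:52) / 52), 3)
#' max(abs(removeSeasonalCycle(x, rep(1:52, 3))$values))
#' @export
removeSeasonalCycle <- function(values, weekOfYear) {
  stopifnot(length(values) == length(weekOfYear))
  w <- as.integer(weekOfYear)
  if (any(w < 1L | w > 52L)) stop("weekOfYear must lie in 1..52")
  means <- rep(NA_real_, 52)
  for (k in unique(w)) {
    v <- values[w == k]
    if (all(is.na(v)))
      stop(sprintf(
        "week of year %d has zero observations across all years", k))
    means[k] <- mean(v, na.rm = TRUE)
  }
  list(values = values - means[w], weeklyMeans = means)
}

#' Jointly fit linear trend and week-of-year climatology
#'
#' One OLS projection of the series on a linear week-index term plus
#' week-of-year indicator terms. Residuals are simultaneously detrended and
#' deseasonalized: they are exactly orthogonal to the trend and have
#' exactly zero mean at every week of year, so an exact
#' periodic-plus-linear input yields anomalies that vanish to machine
#' precision (sequentially applying [detrendLinear()] then
#' [removeSeasonalCycle()] leaves a small leakage term, because a sampled
#' seasonal cycle is not exactly orthogonal to a linear trend).
#'
#' @param values numeric weekly series (missing entries allowed).
#' @param weekOfYear integer labels in 1..52.
#' @param minObs minimum non-missing entries (default 104).
#' @return List: `values` (anomalies; missing stays missing) and `model`
#'   (a [ClimatologyModel-class]).
#' @export
fitClimatology <- function(values, weekOfYear, minObs = 104L) {
  stopifnot(length(values) == length(weekOfYear))
  w <- as.integer(weekOfYear)
  if (any(w < 1L | w > 52L)) stop("weekOfYear must lie in 1..52")
  ok <- !is.na(values)
  if (sum(ok) < minObs)
    stop(sprintf("climatology fit needs >= %d non-missing entries",
                 minObs))
  for (k in unique(w))
    if (!any(ok[w == k]))
      stop(sprintf(
        "week of year %d has zero observations across all years", k))
  lev <- sort(unique(w))
  D <- outer(w[ok], lev, `==`) * 1
  t <- seq_along(values)
  fit <- lm.fit(cbind(D, t[ok] - mean(t[ok])), values[ok])
  cf <- fit$coefficients
  slope <- unname(cf[length(cf)])
  if (is.na(slope)) slope <- 0  # degenerate: trend collinear with cycle
  sw <- rep(NA_real_, 52)
  sw[lev] <- cf[seq_along(lev)]
  out <- rep(NA_real_, length(values))
  out[ok] <- fit$residuals
  icpt <- mean(sw, na.rm = TRUE) - slope * mean(t[ok])
  list(values = out,
       model = climatologyModel(intercept = icpt, slope = slope,
                                weeklyMeans = sw - mean(sw, na.rm = TRUE)))
}

#' Run the standard preprocessing pipeline on a panel
#'
#' Applies, in fixed order: log transform of the target (burned area) only,
#' then per-variable removal of the linear trend and week-of-year seasonal
#' cycle as one joint OLS projection (see [fitClimatology()]). The order is
#' recorded in the output panel's metadata. Confidence masking and weekly
#' aggregation are upstream, pixel-level steps (see [maskLowConfidence()],
#' [aggregateToWeekly()], [aggregateToEcoregion()]).
#'
#' @param panel a [FirePanel-class] of raw weekly series.
#' @param logTarget logical; log1p-transform the target column (default
#'   TRUE).
#' @param logOffset offset of the log transform.
#' @return List with `panel` (anomaly [FirePanel-class]) and `climatology`
#'   (named list of [ClimatologyModel-class], one per variable).
#' @examples
#' p <- generateNullPanel(3, 208, seed = 1)
#' out <- preprocessPanel(p, logTarget = FALSE)
#' panelMetadata(out$panel)$pipeline
#' @export
preprocessPanel <- function(panel, logTarget = TRUE, logOffset = 1) {
  v <- panelValues(panel)
  woy <- weekOfYear(panel)
  tgt <- targetVariable(panel)
  clim <- list()
  steps <- character(0)
  if (logTarget && !is.na(tgt)) {
    v[, tgt] <- logTransformBA(v[, tgt], offset = logOffset)
    steps <- c(steps, "log")
  }
  for (j in colnames(v)) {
    fc <- fitClimatology(v[, j], woy)
    v[, j] <- fc$values
    clim[[j]] <- fc$model
  }
  steps <- c(steps, "detrend", "deseasonalize")
  md <- panelMetadata(panel)
  md$pipeline <- steps
  md$anomalyFit <- "joint-ols"
  out <- firePanel(v, variableGroups(panel), weekOfYear = woy,
                   metadata = md)
  list(panel = out, climatology = clim)
}
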