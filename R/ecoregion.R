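#' @include AllClasses.R
NULL

#' Enumerate ecoregion keys
#'
#' An ecoregion is the intersection of one climate zone and one vegetation
#' type; crossing the 29 usable climate-zone codes with the 8 vegetation
#' classes yields the 232 strata of the global analysis. The cross-product
#' is deterministically ordered climate-major, then vegetation, and the
#' identifier is the `":"`-joined pair.
#'
#' @param climateCodes,vegetationCodes vectors of unique codes.
#' @return data.frame with columns `climate`, `vegetation`, `id`.
#' @examples
#' nrow(buildEcoregionKeys(1:29, 1:8))
#' @export
buildEcoregionKeys <- function(climateCodes, vegetationCodes) {
  if (!length(climateCodes) || !length(vegetationCodes))
    stop("both code lists must be non-empty")
  if (anyDuplicated(climateCodes)) stop("duplicate climate codes")
  if (anyDuplicated(vegetationCodes)) stop("duplicate vegetation codes")
  climate <- rep(climateCodes, each = length(vegetationCodes))
  vegetation <- rep(vegetationCodes, times = length(climateCodes))
  data.frame(climate = climate, vegetation = vegetation,
             id = paste(climate, vegetation, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Block-aggregate a raster to 0.25 degrees
#'
#' Integer block aggregation only: the input resolution must divide 0.25
#' degrees evenly (an input already at 0.25 degrees passes through
#' unchanged); no interpolation is performed. Categorical layers use
#' `method = "mode"` with ties resolved to the lowest code.
#'
#' @param x numeric matrix (rows x cols of grid cells).
#' @param resolution input cell size in degrees.
#' @param method `"mean"`, `"sum"`, or `"mode"`.
#' @return Aggregated matrix at 0.25-degree resolution.
#' @examples
#' regridQuarterDegree(matrix(c(1, 1, 3, 3), 2, 2), 0.125, "mean")
#' @export
regridQuarterDegree <- function(x, resolution,
                                method = c("mean", "sum", "mode")) {
  method <- match.arg(method)
  f <- 0.25 / resolution
  if (abs(f - round(f)) > 1e-9 || f < 1 - 1e-9)
    stop("input resolution must divide 0.25 degrees evenly")
  f <- as.integer(round(f))
  if (f == 1L) return(x)
  if (nrow(x) %% f != 0L || ncol(x) %% f != 0L)
    stop("grid shape must be a multiple of the aggregation factor")
  nr <- nrow(x) %/% f; nc <- ncol(x) %/% f
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- x[(i - 1L) * f + seq_len(f), (j - 1L) * f + seq_len(f)]
      v <- block[!is.na(block)]
      out[i, j] <- if (!length(v)) NA_real_
      else switch(method,
                  mean = mean(v),
                  sum = sum(v),
                  mode = {
                    tab <- table(v)
                    cand <- as.numeric(names(tab)[tab == max(tab)])
                    min(cand)  # tie -> lowest code
                  })
    }
  }
  out
}

#' Collapse a classified scene to per-ecoregion weekly panels
#'
#' Per week, ecoregional burned area is the plain sum of the member pixels'
#' unmasked burned area, and every precursor is the area-weighted mean over
#' member pixels with non-missing values (cosine-of-latitude weights by
#' default; `weighting = "uniform"` gives the unweighted mean). Requested
#' keys with no member pixels are skipped with a warning.
#'
#' @param scene a [ClassifiedScene-class] (mask the burned-area layer first
#'   with [maskLowConfidence()] via `maskThreshold`, or pass
#'   `maskThreshold = NULL` to skip).
#' @param keys data.frame of ecoregion keys (default: all combinations
#'   observed on the grid, climate-major order).
#' @param weighting `"cosine"` or `"uniform"` precursor pixel weights.
#' @param maskThreshold percent confidence below which burned-area
#'   pixel-weeks are masked before summation (default 70; `NULL` disables).
#' @return Named list of raw [FirePanel-class] objects (one per non-empty
#'   key); each panel's metadata records the key, pixel count, total area,
#'   and the number of masked burned-area entries.
#' @export
aggregateToEcoregion <- function(scene, keys = NULL,
                                 weighting = c("cosine", "uniform"),
                                 maskThreshold = 70) {
  weighting <- match.arg(weighting)
  pix <- scene@pixels
  if (is.null(keys))
    keys <- buildEcoregionKeys(sort(unique(pix$climate)),
                               sort(unique(pix$vegetation)))
  vars <- dimnames(scene@data)[[3]]
  tgt <- which(scene@groups == "target")

  ba <- scene@data[, , tgt, drop = FALSE]
  dim(ba) <- dim(scene@data)[1:2]
  nMasked <- 0L
  if (!is.null(maskThreshold)) {
    m <- maskLowConfidence(ba, scene@confidence, maskThreshold)
    ba <- m$values
    nMasked <- m$nMasked
  }

  out <- list()
  for (i in seq_len(nrow(keys))) {
    members <- which(pix$climate == keys$climate[i] &
                       pix$vegetation == keys$vegetation[i])
    if (!length(members)) {
      warning(sprintf("ecoregion %s has no pixels; skipped", keys$id[i]))
      next
    }
    w <- if (weighting == "cosine") pix$area[members]
    else rep(1, length(members))
    v <- matrix(NA_real_, dim(scene@data)[1], length(vars),
                dimnames = list(NULL, vars))
    for (k in seq_along(vars)) {
      if (k == tgt) {
        b <- ba[, members, drop = FALSE]
        allNA <- rowSums(!is.na(b)) == 0L
        v[, k] <- ifelse(allNA, NA_real_, rowSums(b, na.rm = TRUE))
      } else {
        x <- scene@data[, members, k, drop = FALSE]
        dim(x) <- c(dim(scene@data)[1], length(members))
        wm <- matrix(w, nrow(x), length(members), byrow = TRUE)
        wm[is.na(x)] <- NA_real_
        sw <- rowSums(wm, na.rm = TRUE)
        v[, k] <- ifelse(sw > 0,
                         rowSums(x * wm, na.rm = TRUE) / sw, NA_real_)
      }
    }
    out[[keys$id[i]]] <- firePanel(
      v, scene@groups, weekOfYear = scene@weekOfYear,
      metadata = list(ecoregion = keys$id[i],
                      pixelCount = length(members),
                      totalArea = sum(pix$area[members]),
                      weighting = weighting,
                      nMaskedBA = nMasked))
  }
  out
}
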