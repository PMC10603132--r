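#' @include pcmci.R
NULL

#' Links from precursors into the target
#'
#' Filters the retained links of a graph to those pointing at the stated
#' target (burned area); links between precursors, autodependencies, and
#' links out of the target are discarded. Multiple lags of the same
#' precursor are all kept here; collapsing to one link per precursor
#' happens in [rankPrecursors()].
#'
#' @param graph a [CausalGraph-class].
#' @param target target variable identifier (default: the graph's variable
#'   tagged `"target"`).
#' @return data.frame with columns `precursor`, `lag`, `rho`, `pvalue`.
#' @export
linksToTarget <- function(graph, target = NULL) {
  if (is.null(target)) {
    i <- which(graph@groups == "target")
    target <- if (length(i)) graph@variables[i[1]] else
      stop("graph has no target variable; supply one")
  }
  lk <- graph@links
  lk <- lk[lk$target == target & lk$source != target, , drop = FALSE]
  data.frame(precursor = lk$source, lag = lk$lag, rho = lk$rho,
             pvalue = lk$pvalue, stringsAsFactors = FALSE)
}

# Deterministic ordering used everywhere: larger |rho|, then smaller lag,
# then lexicographic identifier.
.rankOrder <- function(absRho, lag, id) order(-absRho, lag, id)

#' Rank precursors by causal strength
#'
#' Collapses the link table to one link per precursor (its strongest, i.e.
#' max `|rho|`, ties resolved to the smaller lag then the lexicographically
#' smaller identifier), then ranks the precursors by that strength with the
#' same tie rule. The first-ranked precursor is the dominant precursor and
#' its lag the dominant time lag.
#'
#' @param table per-link data.frame from [linksToTarget()] (possibly
#'   empty).
#' @return List: `ranking` (collapsed, ordered data.frame), `dominant`
#'   (list with `precursor`, `lag`, `rho`, or `NULL` for an empty table).
#' @examples
#' tb <- data.frame(precursor = c("ET0", "SWDI"), lag = c(1, 60),
#'                  rho = c(0.5, -0.3), pvalue = c(1e-5, 1e-3))
#' rankPrecursors(tb)$dominant
#' @export
rankPrecursors <- function(table) {
  if (!nrow(table))
    return(list(ranking = table, dominant = NULL))
  ord <- .rankOrder(abs(table$rho), table$lag, table$precursor)
  tb <- table[ord, , drop = FALSE]
  tb <- tb[!duplicated(tb$precursor), , drop = FALSE]  # strongest per precursor
  rownames(tb) <- NULL
  list(ranking = tb,
       dominant = list(precursor = tb$precursor[1], lag = tb$lag[1],
                       rho = tb$rho[1]))
}

#' Dominant precursor group
#'
#' The group (top-down or bottom-up) owning the link of maximum `|rho|`
#' among the precursor-to-target links; ties across groups resolve by the
#' [rankPrecursors()] tie rule. An empty table maps to `"none"` (no causal
#' relationship detected).
#'
#' @param table per-link data.frame from [linksToTarget()].
#' @param grouping named character vector mapping precursor to group (see
#'   [defaultGrouping()]).
#' @return List: `group` (`"top-down"`, `"bottom-up"`, or `"none"`),
#'   `strengths` (named numeric, max `|rho|` per group).
#' @export
dominantGroup <- function(table, grouping = defaultGrouping()) {
  if (!nrow(table))
    return(list(group = "none",
                strengths = c(`top-down` = NA_real_,
                              `bottom-up` = NA_real_)))
  rk <- rankPrecursors(table)$ranking
  grp <- unname(grouping[rk$precursor])
  if (anyNA(grp)) stop("unmapped precursor in link table")
  strengths <- vapply(c("top-down", "bottom-up"), function(g) {
    v <- abs(rk$rho[grp == g])
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  list(group = grp[1], strengths = strengths)
}

#' Predictability score of an ecoregion
#'
#' The sum of squared partial correlations of the precursors' strongest
#' links into the target: a dimensionless score in `[0, 10]` for the ten
#' standard precursors, higher meaning the burned area of the ecoregion is
#' better predicted by its precursors. Precursors with no retained link
#' contribute 0; by default only retained (significant) links enter, but
#' a full audit rho vector can be supplied instead.
#'
#' @param table per-link data.frame from [linksToTarget()].
#' @return Non-negative numeric.
#' @examples
#' predictabilityScore(data.frame(precursor = c("A", "B"), lag = c(1, 2),
#'                                rho = c(0.3, -0.4), pvalue = 0))
#' @export
predictabilityScore <- function(table) {
  if (!nrow(table)) return(0)
  sum(rankPrecursors(table)$ranking$rho^2)
}

#' Correlation-weighted mean time lag
#'
#' `sum(|rho_i| * lag_i) / sum(|rho_i|)` over the collapsed (one strongest
#' link per precursor) link table. Absolute correlations are used as
#' weights: signed weights could cancel to a zero denominator and a
#' negative importance is uninterpretable.
#'
#' @param table non-empty per-link data.frame from [linksToTarget()].
#' @return Numeric lag in weeks, within the range of the input lags.
#' @examples
#' weightedMeanLag(data.frame(precursor = c("A", "B"), lag = c(2, 8),
#'                            rho = c(0.4, 0.2), pvalue = 0))  # 4
#' @export
weightedMeanLag <- function(table) {
  if (!nrow(table)) stop("weightedMeanLag needs a non-empty link table")
  rk <- rankPrecursors(table)$ranking
  sum(abs(rk$rho) * rk$lag) / sum(abs(rk$rho))
}

#' Attribute dominance for one ecoregion
#'
#' Bundles the per-ecoregion headline quantities into a
#' [DominanceRecord-class]: dominant group and precursor with its lag,
#' predictability score, the collapsed per-precursor link table, and the
#' `|rho|`-weighted mean lag of each group's links.
#'
#' @param graph a [CausalGraph-class] for the ecoregion.
#' @param grouping precursor-to-group mapping; `NULL` derives it from the
#'   graph's own variable group tags.
#' @param ecoregion identifier stored on the record.
#' @param area area weight of the ecoregion (default 1).
#' @param target target variable (default from the graph).
#' @return A [DominanceRecord-class].
#' @export
attributeDominance <- function(graph, grouping = NULL,
                               ecoregion = "ecoregion", area = 1,
                               target = NULL) {
  if (is.null(grouping))
    grouping <- setNames(graph@groups, graph@variables)
  tb <- linksToTarget(graph, target)
  rk <- rankPrecursors(tb)
  dg <- dominantGroup(tb, grouping)
  links <- rk$ranking
  if (nrow(links)) {
    links$group <- unname(grouping[links$precursor])
    links <- links[, c("precursor", "group", "lag", "rho", "pvalue")]
  } else {
    links <- data.frame(precursor = character(0), group = character(0),
                        lag = integer(0), rho = numeric(0),
                        pvalue = numeric(0), stringsAsFactors = FALSE)
  }
  gl <- vapply(c("top-down", "bottom-up"), function(g) {
    sub <- links[links$group == g, , drop = FALSE]
    if (!nrow(sub)) NA_real_ else
      sum(abs(sub$rho) * sub$lag) / sum(abs(sub$rho))
  }, numeric(1))
  new("DominanceRecord",
      ecoregion = as.character(ecoregion), area = as.numeric(area),
      dominantGroup = dg$group,
      dominantPrecursor = if (is.null(rk$dominant)) NA_character_ else
        rk$dominant$precursor,
      dominantLag = if (is.null(rk$dominant)) NA_real_ else
        as.numeric(rk$dominant$lag),
      score = predictabilityScore(tb),
      links = links, groupMeanLags = gl)
}

#' Tabulate a list of dominance records
#'
#' @param records list of [DominanceRecord-class].
#' @return data.frame with one row per ecoregion: `ecoregion`, `area`,
#'   `dominantGroup`, `dominantPrecursor`, `dominantLag`, `score`,
#'   `topDownLag`, `bottomUpLag`, `nLinks`.
#' @export
dominanceTable <- function(records) {
  do.call(rbind, lapply(records, function(r)
    data.frame(ecoregion = r@ecoregion, area = r@area,
               dominantGroup = r@dominantGroup,
               dominantPrecursor = r@dominantPrecursor,
               dominantLag = r@dominantLag, score = r@score,
               topDownLag = r@groupMeanLags[["top-down"]],
               bottomUpLag = r@groupMeanLags[["bottom-up"]],
               nLinks = nrow(r@links), stringsAsFactors = FALSE,
               row.names = NULL)))
}

#' Sign fractions of partial correlations per group
#'
#' For each group, over the ecoregions where that group is dominant, the
#' fractions of its links with positive and negative partial correlation.
#' Fractions sum to 1; an exactly zero rho (a measure-zero event) counts as
#' positive by a deterministic rule.
#'
#' @param records list of [DominanceRecord-class].
#' @return data.frame: `group`, `positive`, `negative`, `nLinks`.
#' @export
signFractions <- function(records) {
  out <- lapply(c("top-down", "bottom-up"), function(g) {
    rhos <- unlist(lapply(records, function(r) {
      if (r@dominantGroup != g) return(numeric(0))
      r@links$rho[r@links$group == g]
    }))
    n <- length(rhos)
    data.frame(group = g,
               positive = if (n) mean(rhos >= 0) else NA_real_,
               negative = if (n) mean(rhos < 0) else NA_real_,
               nLinks = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Area-weighted group mean lag across ecoregions
#'
#' The group's characteristic time lag: the area-weighted mean of its
#' per-ecoregion `|rho|`-weighted mean lags, over the ecoregions where the
#' group is dominant.
#'
#' @param records list of [DominanceRecord-class].
#' @param group `"top-down"` or `"bottom-up"`.
#' @return Numeric lag in weeks.
#' @export
groupMeanLag <- function(records, group) {
  sel <- Filter(function(r) r@dominantGroup == group, records)
  if (!length(sel))
    stop(sprintf("no ecoregion has dominant group '%s'", group))
  lag <- vapply(sel, function(r) r@groupMeanLags[[group]], numeric(1))
  area <- vapply(sel, function(r) r@area, numeric(1))
  sum(area * lag) / sum(area)
}

#' Covariate-binned dominance profile
#'
#' Bins pixels into `nBins` equal-width bins over the observed range of a
#' covariate (e.g. mean Tmax, VPD, EVI, or latitude) and computes, per bin,
#' the fraction of pixels dominated by each group (number of pixels with
#' that dominant group divided by the number of pixels dominated by either
#' group; undetected pixels are excluded from the denominator) plus the
#' area-weighted mean lag of each group's dominated pixels. Bins with no
#' dominated pixel are flagged undefined (`NA` fractions).
#'
#' @param pixels data.frame with columns `value` (covariate),
#'   `dominantGroup`, `lag` (the pixel's ecoregion group mean lag), `area`.
#' @param nBins number of bins (default 200).
#' @return data.frame with one row per bin: `bin`, `lower`, `upper`, `mid`,
#'   `n`, `nDominated`, `topDownFraction`, `bottomUpFraction`,
#'   `topDownLag`, `bottomUpLag`. Bin edges are also attached as the
#'   `edges` attribute.
#' @export
binnedDominanceProfile <- function(pixels, nBins = 200L) {
  stopifnot(all(c("value", "dominantGroup", "area") %in% names(pixels)))
  if (!"lag" %in% names(pixels)) pixels$lag <- NA_real_
  rng <- range(pixels$value, na.rm = TRUE)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- findInterval(pixels$value, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- data.frame(bin = seq_len(nBins),
                    lower = edges[-(nBins + 1L)], upper = edges[-1])
  out$mid <- (out$lower + out$upper) / 2
  out$n <- integer(nBins)
  out$nDominated <- integer(nBins)
  out$topDownFraction <- NA_real_
  out$bottomUpFraction <- NA_real_
  out$topDownLag <- NA_real_
  out$bottomUpLag <- NA_real_
  grp <- pixels$dominantGroup
  for (k in seq_len(nBins)) {
    inb <- bin == k & !is.na(pixels$value)
    dom <- inb & grp %in% c("top-down", "bottom-up")
    out$n[k] <- sum(inb)
    out$nDominated[k] <- sum(dom)
    if (out$nDominated[k] == 0L) {
      out$topDownFraction[k] <- NA_real_
      out$bottomUpFraction[k] <- NA_real_
      out$topDownLag[k] <- NA_real_
      out$bottomUpLag[k] <- NA_real_
      next
    }
    out$topDownFraction[k] <- sum(grp[dom] == "top-down") /
      out$nDominated[k]
    out$bottomUpFraction[k] <- sum(grp[dom] == "bottom-up") /
      out$nDominated[k]
    for (g in c("top-down", "bottom-up")) {
      sel <- dom & grp == g & !is.na(pixels$lag)
      val <- if (sum(sel)) sum(pixels$area[sel] * pixels$lag[sel]) /
        sum(pixels$area[sel]) else NA_real_
      if (g == "top-down") out$topDownLag[k] <- val else
        out$bottomUpLag[k] <- val
    }
  }
  attr(out, "edges") <- edges
  out
}

#' Dominance fractions per climate zone and vegetation type
#'
#' Per stratum, the number of pixels dominated by each group divided by the
#' number of pixels dominated by either group (pixels with no detected
#' relationship are excluded from the denominator). Strata with no
#' dominated pixel are flagged undefined.
#'
#' @param pixels data.frame with columns `climate`, `vegetation`,
#'   `dominantGroup`.
#' @return List of two data.frames (`climate`, `vegetation`), each with
#'   `stratum`, `topDownFraction`, `bottomUpFraction`, `nDominated`.
#' @export
zoneTypeDominance <- function(pixels) {
  strat <- function(key) {
    out <- lapply(split(pixels, pixels[[key]]), function(d) {
      dom <- d$dominantGroup %in% c("top-down", "bottom-up")
      n <- sum(dom)
      data.frame(stratum = as.character(d[[key]][1]),
                 topDownFraction = if (n)
                   sum(d$dominantGroup[dom] == "top-down") / n else NA_real_,
                 bottomUpFraction = if (n)
                   sum(d$dominantGroup[dom] == "bottom-up") / n else
                     NA_real_,
                 nDominated = n, stringsAsFactors = FALSE)
    })
    r <- do.call(rbind, out)
    rownames(r) <- NULL
    r
  }
  list(climate = strat("climate"), vegetation = strat("vegetation"))
}
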