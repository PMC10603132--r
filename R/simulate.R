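#' @include scenario.R
NULL

# Topological order of the contemporaneous (lag-0) links so that a source is
# always materialized before the targets it feeds within the same week.
.orderLinks <- function(sys, nv) {
  if (!length(sys$src)) return(integer(0))
  idx <- seq_along(sys$src)
  lag0 <- idx[sys$lag == 0L]
  if (!length(lag0)) return(idx)
  ordered <- idx[sys$lag > 0L]
  done <- rep(FALSE, length(lag0))
  resolved <- logical(nv)
  # variables never appearing as lag-0 targets are roots
  resolved[setdiff(seq_len(nv), sys$tgt[lag0])] <- TRUE
  repeat {
    ready <- which(!done & resolved[sys$src[lag0]])
    if (!length(ready)) break
    for (i in ready) {
      ordered <- c(ordered, lag0[i])
      done[i] <- TRUE
    }
    for (v in seq_len(nv)) {
      if (!resolved[v] && all(done[sys$tgt[lag0] == v])) resolved[v] <- TRUE
    }
  }
  if (!all(done))
    stop("contemporaneous planted links form a cycle")
  ordered
}

# Zero-inflated skew marginal for burned area: exact zeros at/below the
# threshold, expm1 of the excess above it elsewhere.
.baTransform <- function(z, threshold) {
  ifelse(z <= threshold, 0, expm1(z - threshold))
}

.seasonTrend <- function(spec) {
  t <- seq_len(spec@nWeeks)
  per <- spec@seasonalPeriod
  outer(sin(2 * pi * t / per), spec@seasonalAmplitude) +
    outer(t, spec@trendSlope)
}

#' Simulate a synthetic weekly panel with planted causal structure
#'
#' Draws Gaussian innovations, runs the planted lagged linear system (with a
#' burn-in so the process is effectively stationary), adds the declared
#' seasonal cycle and linear trend, and — if requested — renders the target
#' through the zero-inflated expm1 marginal so the observed burned-area
#' series is non-negative, right-skewed, and has exact zero weeks. The
#' planted links are returned verbatim in the panel metadata, together with
#' the latent (pre-transform) standard deviation of every variable.
#'
#' Identical `(spec, seed)` gives bit-identical output.
#'
#' @param spec a [ScenarioSpec-class].
#' @return A [FirePanel-class]; `panelMetadata(x)$groundTruth` holds the
#'   planted link table, `$latentSd` the stationary standard deviations of
#'   the latent anomalies, and `$latentTarget` the pre-transform target
#'   series (used by the scene generator).
#' @examples
#' sc <- scenarioSpec(c("X", "BA"), c("top-down", "target"),
#'                    links = plantedLink("X", "BA", 2, 0.6),
#'                    nWeeks = 400, seed = 7)
#' p <- simulatePanel(sc)
#' cor(panelValues(p)[1:398, "X"], panelValues(p)[3:400, "BA"])
#' @export
simulatePanel <- function(spec) {
  validObject(spec)
  nv <- length(spec@variables)
  T <- spec@nWeeks
  maxLag <- max(c(0L, spec@links$lag, if (any(spec@arCoef != 0)) 1L))
  burn <- 200L + 3L * maxLag

  set.seed(spec@seed)
  eps <- matrix(rnorm((burn + T) * nv), burn + T, nv) %*% diag(spec@noiseSd,
                                                               nv)
  sys <- .systemLinks(spec)
  ord <- .orderLinks(sys, nv)
  if (length(ord)) {
    z <- var_recurse(eps, as.integer(sys$src[ord] - 1L),
                     as.integer(sys$tgt[ord] - 1L),
                     as.integer(sys$lag[ord]), as.numeric(sys$coef[ord]))
  } else {
    z <- eps
  }
  z <- z[burn + seq_len(T), , drop = FALSE]
  colnames(z) <- spec@variables

  obs <- z + .seasonTrend(spec)
  latentSd <- apply(z, 2, sd)

  tgt <- which(spec@groups == "target")
  latentTarget <- obs[, tgt]
  baThreshold <- NA_real_
  if (spec@baSkewTransform) {
    # shift by the zero-inflation quantile so the observed series is
    # non-negative with exact zeros below the threshold; log1p recovers the
    # latent series (minus a constant) on the nonzero weeks
    baThreshold <- quantile(latentTarget, spec@baZeroInflation, names = FALSE)
    obs[, tgt] <- .baTransform(latentTarget, baThreshold)
  }

  firePanel(obs, spec@groups,
            weekOfYear = rep_len(1:52, T),
            metadata = list(groundTruth = spec@links,
                            latentSd = latentSd,
                            latentTarget = latentTarget,
                            baThreshold = baThreshold,
                            scenarioSeed = spec@seed))
}

#' Simulate a panel of mutually independent white-noise series
#'
#' The global-null benchmark used to calibrate the false-positive rate of
#' the conditional-independence machinery: `nVars` standard Gaussian series
#' with no links, no season, and no trend. The last variable is tagged as
#' the target (the tagging is irrelevant under the null).
#'
#' @param nVars number of series (>= 2).
#' @param nWeeks series length (>= 100).
#' @param seed integer RNG seed.
#' @return A [FirePanel-class] with an empty ground-truth link table.
#' @examples
#' p <- generateNullPanel(5, 500, seed = 1)
#' dim(panelValues(p))
#' @export
generateNullPanel <- function(nVars, nWeeks, seed) {
  stopifnot(nVars >= 2, nWeeks >= 100)
  vars <- paste0("X", seq_len(nVars))
  groups <- rep(c("top-down", "bottom-up"), length.out = nVars)
  groups[nVars] <- "target"
  sc <- scenarioSpec(vars, groups, nWeeks = nWeeks, seed = seed)
  simulatePanel(sc)
}
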