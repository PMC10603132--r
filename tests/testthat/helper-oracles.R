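# Independent oracles and small fixture builders, computed with different
# code paths than the package internals.

# Brute-force partial correlation: explicit double regression via lm(),
# then Pearson on the residuals.
oraclePcor <- function(x, y, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) return(cor(x, y))
  Z <- as.matrix(Z)
  rx <- stats::resid(stats::lm(x ~ Z))
  ry <- stats::resid(stats::lm(y ~ Z))
  cor(rx, ry)
}

# Closed-form partial correlation of (1,2) given the rest, from the
# precision matrix of a covariance.
oraclePcorSigma <- function(Sigma) {
  P <- solve(Sigma)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Sample skewness (method-of-moments).
sampleSkewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

# A minimal two-variable scenario with one planted link.
oneLinkScenario <- function(lag = 2L, coefficient = 0.6, nWeeks = 500L,
                            seed = 1L, ...) {
  scenarioSpec(c("X", "BA"), c("top-down", "target"),
               links = plantedLink("X", "BA", lag, coefficient),
               nWeeks = nWeeks, seed = seed, ...)
}

# The standard 11-variable panel with two planted links into burned area.
twoLinkScenario <- function(seed = 1L, nWeeks = 936L,
                            tdLag = 1L, tdCoef = 0.7,
                            buLag = 60L, buCoef = -0.4) {
  grouping <- defaultGrouping()
  scenarioSpec(c("BA", names(grouping)), c("target", unname(grouping)),
               links = rbind(plantedLink("Tmax", "BA", tdLag, tdCoef),
                             plantedLink("SWDI", "BA", buLag, buCoef)),
               nWeeks = nWeeks, seed = seed,
               arCoef = c(0, rep(0.5, 10)))
}

# A tiny scene: each ecoregion one column of pixels, one planted link.
tinyScene <- function(nEco = 2, pixelsPer = 2, nWeeks = 300L, seed = 1L,
                      pixelNoiseSd = 0.1, links = NULL, ...) {
  climate <- matrix(rep(seq_len(nEco), each = pixelsPer),
                    nrow = pixelsPer)
  veg <- matrix(1L, pixelsPer, nEco)
  scen <- list()
  for (e in seq_len(nEco)) {
    lk <- if (is.null(links)) plantedLink("X", "BA", 1, 0.6) else
      links[[e]]
    scen[[paste(e, 1, sep = ":")]] <-
      scenarioSpec(c("X", "S", "BA"),
                   c("top-down", "bottom-up", "target"),
                   links = lk, nWeeks = nWeeks, seed = seed + e,
                   baZeroInflation = 0.3, baSkewTransform = TRUE, ...)
  }
  sceneSpec(climate, veg, scen, pixelNoiseSd = pixelNoiseSd, seed = seed)
}
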