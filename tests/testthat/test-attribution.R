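mkTable <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(precursor = r[[1]], lag = as.numeric(r[[2]]),
               rho = as.numeric(r[[3]]), pvalue = 1e-4,
               stringsAsFactors = FALSE)))
}
emptyTable <- data.frame(precursor = character(0), lag = numeric(0),
                         rho = numeric(0), pvalue = numeric(0))

test_that("target link filtering keeps only precursor-to-target links", {
  sc <- oneLinkScenario(nWeeks = 300, seed = 61)
  g <- runPCMCI(simulatePanel(sc), pcmciConfig(tauMax = 5))
  tb <- linksToTarget(g)
  expect_true(all(tb$precursor != "BA"))
  lk <- causalLinks(g)
  expect_identical(nrow(tb),
                   sum(lk$target == "BA" & lk$source != "BA"))
})

test_that("precursor ranking uses |rho| with lag and name tie-breaks", {
  tb <- mkTable(list("ET0", 1, 0.5), list("SWDI", 60, -0.3))
  d <- rankPrecursors(tb)$dominant
  expect_identical(d$precursor, "ET0")
  expect_identical(d$lag, 1)

  # tie on |rho|: smaller lag wins
  tie <- mkTable(list("GPP", 4, -0.4), list("VPD", 0, 0.4))
  expect_identical(rankPrecursors(tie)$dominant$precursor, "VPD")

  single <- mkTable(list("NDVI", 7, -0.2))
  expect_identical(rankPrecursors(single)$dominant$precursor, "NDVI")

  # two lags of one precursor collapse to the strongest
  two <- mkTable(list("ET0", 1, 0.5), list("ET0", 9, -0.7))
  rk <- rankPrecursors(two)$ranking
  expect_identical(nrow(rk), 1L)
  expect_identical(rk$lag, 9)

  expect_null(rankPrecursors(emptyTable)$dominant)
})

test_that("dominant group follows the strongest link and maps 'none'", {
  tb <- mkTable(list("SWDI", 30, -0.6), list("Tmax", 1, 0.4))
  expect_identical(dominantGroup(tb)$group, "bottom-up")
  expect_identical(dominantGroup(emptyTable)$group, "none")
  tie <- mkTable(list("GPP", 4, -0.4), list("VPD", 0, 0.4))
  expect_identical(dominantGroup(tie)$group, "top-down")
})

test_that("predictability score sums squared strongest-link correlations", {
  expect_equal(predictabilityScore(mkTable(list("A", 1, 0.3),
                                           list("B", 2, -0.4))), 0.25)
  expect_equal(predictabilityScore(emptyTable), 0)
  all10 <- do.call(mkTable, lapply(names(defaultGrouping()),
                                   function(v) list(v, 1, 1)))
  expect_equal(predictabilityScore(all10), 10)

  # invariant to row order, monotone in each |rho|
  tb <- mkTable(list("A", 1, 0.3), list("B", 2, -0.4), list("C", 5, 0.1))
  expect_equal(predictabilityScore(tb[c(3, 1, 2), ]),
               predictabilityScore(tb))
  tb2 <- tb; tb2$rho[3] <- 0.5
  expect_gt(predictabilityScore(tb2), predictabilityScore(tb))
})

test_that("correlation-weighted mean lag matches hand evaluation", {
  expect_equal(weightedMeanLag(mkTable(list("A", 4, 0.9))), 4)
  expect_equal(weightedMeanLag(mkTable(list("A", 2, 0.4),
                                       list("B", 8, 0.2))), 4)
  cstLag <- mkTable(list("A", 6, 0.7), list("B", 6, -0.1))
  expect_equal(weightedMeanLag(cstLag), 6)
  tb <- mkTable(list("A", 2, 0.5), list("B", 11, -0.2))
  wl <- weightedMeanLag(tb)
  expect_true(wl >= 2 && wl <= 11)
  expect_error(weightedMeanLag(emptyTable), "non-empty")
})

mkRecord <- function(eco, group, rhos, lags, area = 1) {
  links <- data.frame(precursor = paste0("P", seq_along(rhos)),
                      group = group, lag = lags, rho = rhos,
                      pvalue = 1e-4, stringsAsFactors = FALSE)
  ord <- order(-abs(rhos), lags)
  links <- links[ord, ]
  gl <- setNames(c(NA_real_, NA_real_), c("top-down", "bottom-up"))
  gl[group] <- sum(abs(links$rho) * links$lag) / sum(abs(links$rho))
  new("DominanceRecord", ecoregion = eco, area = area,
      dominantGroup = group, dominantPrecursor = links$precursor[1],
      dominantLag = as.numeric(links$lag[1]), score = sum(rhos^2),
      links = links, groupMeanLags = gl)
}

test_that("sign fractions count links of dominant groups only", {
  r1 <- mkRecord("e1", "top-down", c(0.2, 0.5), c(1, 2))
  expect_equal(signFractions(list(r1))$positive[1], 1)
  r2 <- mkRecord("e2", "top-down", c(0.2, -0.2), c(1, 2))
  sf <- signFractions(list(r2))
  expect_equal(sf$positive[1], 0.5)
  expect_equal(sf$negative[1], 0.5)
  # pooled across records; bottom-up undefined when never dominant
  sf2 <- signFractions(list(r1, r2))
  expect_equal(sf2$positive[sf2$group == "top-down"], 0.75)
  expect_true(is.na(sf2$positive[sf2$group == "bottom-up"]))
  # exact zero counts as positive by the deterministic rule
  r3 <- mkRecord("e3", "bottom-up", c(0, -0.4), c(3, 9))
  expect_equal(signFractions(list(r3))$positive[2], 0.5)
})

test_that("group mean lag is the area-weighted mean over dominant strata", {
  a <- mkRecord("e1", "top-down", 0.5, 2, area = 1)
  b <- mkRecord("e2", "top-down", 0.5, 6, area = 1)
  expect_equal(groupMeanLag(list(a, b), "top-down"), 4)
  c1 <- mkRecord("e3", "bottom-up", -0.5, 0, area = 1)
  c2 <- mkRecord("e4", "bottom-up", -0.5, 8, area = 3)
  expect_equal(groupMeanLag(list(c1, c2), "bottom-up"), 6)
  expect_equal(groupMeanLag(list(a), "top-down"), 2)
  expect_error(groupMeanLag(list(a), "bottom-up"), "no ecoregion")
})

test_that("binned dominance profiles count, normalize and flag bins", {
  px <- data.frame(value = c(0.1, 0.2, 0.3, 0.4),
                   dominantGroup = c("top-down", "top-down", "top-down",
                                     "bottom-up"),
                   lag = c(1, 1, 2, 30), area = 1)
  pr <- binnedDominanceProfile(px, nBins = 1L)
  expect_equal(pr$topDownFraction, 0.75)
  expect_equal(pr$bottomUpFraction, 0.25)

  # undominated bin flagged undefined; fractions sum to 1 where defined
  px2 <- rbind(px, data.frame(value = 9, dominantGroup = "none",
                              lag = NA, area = 1))
  pr2 <- binnedDominanceProfile(px2, nBins = 10L)
  expect_true(is.na(pr2$topDownFraction[10]))
  defined <- !is.na(pr2$topDownFraction)
  expect_true(all(abs(pr2$topDownFraction[defined] +
                        pr2$bottomUpFraction[defined] - 1) < 1e-12))

  # a planted step in dominance is recovered at the threshold bin
  set.seed(5)
  v <- runif(4000)
  px3 <- data.frame(value = v,
                    dominantGroup = ifelse(v < 0.6, "top-down",
                                           "bottom-up"),
                    lag = 1, area = 1)
  pr3 <- binnedDominanceProfile(px3, nBins = 200L)
  est <- pr3$mid[min(which(pr3$bottomUpFraction > 0.5))]
  expect_lt(abs(est - 0.6), 2 * (max(v) - min(v)) / 200)
})

test_that("zone and type dominance fractions use the dominated denominator", {
  px <- data.frame(climate = c(1, 1, 1, 1), vegetation = c(2, 2, 2, 2),
                   dominantGroup = c("top-down", "top-down", "bottom-up",
                                     "none"))
  zt <- zoneTypeDominance(px)
  expect_equal(zt$climate$topDownFraction, 2 / 3)
  expect_equal(zt$climate$bottomUpFraction, 1 / 3)
  expect_identical(zt$climate$nDominated, 3L)

  allNone <- data.frame(climate = 1, vegetation = 1,
                        dominantGroup = "none")
  expect_true(is.na(zoneTypeDominance(allNone)$climate$topDownFraction))
  allTD <- data.frame(climate = 2, vegetation = 3,
                      dominantGroup = rep("top-down", 4))
  expect_equal(zoneTypeDominance(allTD)$climate$topDownFraction, 1)
})

test_that("attributeDominance bundles a consistent record", {
  sc <- twoLinkScenario(seed = 71, nWeeks = 600, buLag = 12L)
  g <- runPCMCI(simulatePanel(sc), pcmciConfig(tauMax = 20))
  rec <- attributeDominance(g, ecoregion = "5:2", area = 2.5)
  expect_s4_class(rec, "DominanceRecord")
  expect_true(validObject(rec))
  expect_identical(rec@ecoregion, "5:2")
  expect_identical(rec@dominantGroup, "top-down")
  expect_identical(rec@dominantPrecursor, "Tmax")
  tab <- dominanceTable(list(rec))
  expect_identical(tab$dominantPrecursor, "Tmax")
  expect_equal(tab$score, rec@score)
})
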