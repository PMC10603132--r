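test_that("a link-free scenario yields independent white noise", {
  sc <- scenarioSpec(paste0("X", 1:4),
                     c("top-down", "bottom-up", "top-down", "target"),
                     nWeeks = 2000, seed = 3)
  v <- panelValues(simulatePanel(sc))
  n <- nrow(v)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(cor(v[, i], v[, j])), 3 / sqrt(n))
  # lagged cross-correlation too
  expect_lt(abs(cor(v[1:(n - 3), 1], v[4:n, 2])), 3 / sqrt(n))
})

test_that("single planted link reproduces its Yule-Walker cross-correlation", {
  # X white noise sd 1, BA_t = 0.6 X_{t-2} + e_t: corr(X_{t-2}, BA_t)
  # = 0.6 / sqrt(1 + 0.36)
  rhoPop <- 0.6 / sqrt(1.36)
  sc <- oneLinkScenario(lag = 2L, coefficient = 0.6, nWeeks = 2000,
                        seed = 5)
  v <- panelValues(simulatePanel(sc))
  n <- nrow(v)
  r <- cor(v[1:(n - 2), "X"], v[3:n, "BA"])
  se <- (1 - rhoPop^2) / sqrt(n)
  expect_lt(abs(r - rhoPop), 3 * se)
})

test_that("simulation is deterministic given (spec, seed)", {
  sc <- twoLinkScenario(seed = 9, nWeeks = 400, buLag = 20L)
  p1 <- simulatePanel(sc)
  p2 <- simulatePanel(sc)
  expect_identical(panelValues(p1), panelValues(p2))
  expect_identical(panelMetadata(p1)$groundTruth,
                   panelMetadata(p2)$groundTruth)
})

test_that("unstable or malformed scenarios are rejected with diagnostics", {
  expect_error(scenarioSpec(c("X", "BA"), c("top-down", "target"),
                            arCoef = c(1.05, 0), nWeeks = 300),
               "unstable|spectral")
  expect_error(scenarioSpec(c("X", "BA"), c("top-down", "target"),
                            links = plantedLink("X", "BA", 0, 0.5) |>
                              transform(source = "BA"),
                            nWeeks = 300),
               "self-link")
  expect_error(scenarioSpec(c("X", "BA"), c("top-down", "target"),
                            links = plantedLink("X", "BA", 150, 0.5),
                            nWeeks = 300),
               "nWeeks")
})

test_that("spectral radius matches the driving autoregression", {
  # pure AR(1) with coefficient 0.7: spectral radius 0.7
  sc <- scenarioSpec(c("X", "BA"), c("top-down", "target"),
                     arCoef = c(0.7, 0), nWeeks = 300)
  expect_equal(spectralRadius(sc), 0.7, tolerance = 1e-10)
})

test_that("null panels are independent with the declared shape", {
  p <- generateNullPanel(5, 500, seed = 1)
  expect_identical(dim(panelValues(p)), c(500L, 5L))
  expect_identical(nrow(panelMetadata(p)$groundTruth), 0L)
  p2 <- generateNullPanel(2, 100000, seed = 7)
  v <- panelValues(p2)
  expect_lt(abs(cor(v[, 1], v[, 2])), 3 / sqrt(100000))
  expect_error(generateNullPanel(1, 500, 1))
  expect_error(generateNullPanel(3, 50, 1))
})

test_that("declared season and trend subtract away to stationarity", {
  sc <- scenarioSpec(c("X", "BA"), c("top-down", "target"),
                     seasonalAmplitude = c(2, 1), trendSlope = c(0.01, 0),
                     nWeeks = 936, seed = 11)
  v <- panelValues(simulatePanel(sc))
  t <- seq_len(nrow(v))
  for (j in 1:2) {
    resid <- v[, j] - sc@seasonalAmplitude[j] * sin(2 * pi * t / 52) -
      sc@trendSlope[j] * t
    woy <- rep_len(1:52, length(t))
    for (k in c(1, 13, 26, 40)) {
      x <- resid[woy == k]
      expect_lt(abs(mean(x)), 4 * sd(x) / sqrt(length(x)))
    }
  }
})

test_that("skew-transformed burned area is zero-inflated and log-recoverable", {
  sc <- oneLinkScenario(nWeeks = 1000, seed = 13,
                        baZeroInflation = 0.4, baSkewTransform = TRUE)
  p <- simulatePanel(sc)
  ba <- panelValues(p)[, "BA"]
  expect_true(all(ba >= 0))
  expect_equal(mean(ba == 0), 0.4, tolerance = 0.01)
  # log1p on nonzero weeks recovers the latent series minus its threshold
  md <- panelMetadata(p)
  nz <- ba > 0
  expect_equal(log1p(ba[nz]), md$latentTarget[nz] - md$baThreshold,
               tolerance = 1e-12)
})

test_that("zero pixel noise makes every pixel track its ecoregion signal", {
  scn <- simulateScene(tinyScene(nEco = 1, pixelsPer = 4,
                                 pixelNoiseSd = 0))
  d <- scn@data
  for (px in 2:4) expect_equal(d[, px, ], d[, 1, ], tolerance = 1e-12)
})

test_that("planted dominance labels follow the strongest standardized link", {
  links <- list(plantedLink("X", "BA", 1, 0.6),    # top-down
                plantedLink("S", "BA", 10, -0.6))  # bottom-up
  scn <- simulateScene(tinyScene(nEco = 2, links = links))
  gt <- sceneGroundTruth(scn)
  expect_setequal(gt$dominantGroup, c("top-down", "bottom-up"))
})

test_that("confidence layer mass below threshold matches its distribution", {
  sp <- tinyScene(nEco = 2, pixelsPer = 3, nWeeks = 500)
  sp@confidenceLevels <- c(40, 60, 90)
  sp@confidenceProbs <- c(0.1, 0.2, 0.7)  # 30% below a 70% threshold
  scn <- simulateScene(sp)
  frac <- mean(scn@confidence < 70)
  n <- length(scn@confidence)
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})
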