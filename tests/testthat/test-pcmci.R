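test_that("partial correlation reduces to Pearson and handles identities", {
  set.seed(1)
  x <- rnorm(100)
  expect_equal(partialCorrelation(x, x)$rho, 1, tolerance = 1e-12)
  y <- rnorm(100)
  expect_identical(partialCorrelation(x, y)$rho, cor(x, y))  # exact
})

test_that("partial correlation matches closed form and brute-force oracle", {
  # trivariate Gaussian with known covariance
  Sigma <- matrix(c(1, 0.6, 0.5,
                    0.6, 1, 0.4,
                    0.5, 0.4, 1), 3, 3)
  rhoPop <- oraclePcorSigma(Sigma)
  set.seed(2)
  L <- chol(Sigma)
  n <- 4000
  X <- matrix(rnorm(n * 3), n, 3) %*% L
  res <- partialCorrelation(X[, 1], X[, 2], X[, 3])
  se <- (1 - rhoPop^2) / sqrt(n)
  expect_lt(abs(res$rho - rhoPop), 3 * se)
  expect_lt(abs(res$rho - oraclePcor(X[, 1], X[, 2], X[, 3])), 1e-10)

  # random instances across n and conditioning dimension
  set.seed(3)
  for (i in 1:200) {
    n <- sample(50:500, 1)
    k <- sample(0:5, 1)
    Z <- if (k) matrix(rnorm(n * k), n, k) else NULL
    x <- rnorm(n); y <- rnorm(n)
    if (k && runif(1) < 0.5) {  # correlated case
      x <- x + Z %*% rnorm(k); y <- y + Z %*% rnorm(k)
    }
    expect_lt(abs(partialCorrelation(x, y, Z)$rho - oraclePcor(x, y, Z)),
              1e-10)
  }
})

test_that("degenerate and collinear conditioning is handled gracefully", {
  set.seed(4)
  x <- rnorm(60); y <- rnorm(60)
  z <- rnorm(60)
  expect_warning(res <- partialCorrelation(x, y, cbind(z, 2 * z)),
                 "redundant")
  expect_equal(res$rho, oraclePcor(x, y, z), tolerance = 1e-10)

  cst <- partialCorrelation(rep(1, 60), y)
  expect_true(cst$degenerate)
  expect_identical(cst$pvalue, 1)

  expect_error(partialCorrelation(rnorm(11), rnorm(11)), "sample")
  # listwise deletion over missing entries
  x[5] <- NA
  res2 <- partialCorrelation(x, y, z)
  expect_identical(res2$n, 59L)
  expect_equal(res2$rho, oraclePcor(x[-5], y[-5], z[-5]),
               tolerance = 1e-10)
})

test_that("PC selection finds planted parents and prunes mediated ones", {
  cfg <- pcmciConfig(tauMax = 5)
  hitsDirect <- 0L
  for (s in 1:10) {
    sc <- oneLinkScenario(lag = 2L, coefficient = 0.6, nWeeks = 1000,
                          seed = s)
    p <- simulatePanel(sc)
    pa <- pcConditionSelection(p, "BA", cfg)
    xcol <- match("X", colnames(panelValues(p)))
    if (any(pa$var == xcol & pa$lag == 2L)) hitsDirect <- hitsDirect + 1L
  }
  expect_gte(hitsDirect, 9L)

  # chain X ->(1) Y ->(1) Z: conditioning on (Y,1) removes (X,2) from Z's
  # parent set
  removed <- 0L
  for (s in 1:10) {
    sc <- scenarioSpec(c("X", "Y", "Z"),
                       c("top-down", "bottom-up", "target"),
                       links = rbind(plantedLink("X", "Y", 1, 0.7),
                                     plantedLink("Y", "Z", 1, 0.7)),
                       nWeeks = 5000, seed = 100 + s)
    p <- simulatePanel(sc)
    pa <- pcConditionSelection(p, "Z", pcmciConfig(tauMax = 4))
    ycol <- match("Y", colnames(panelValues(p)))
    xcol <- match("X", colnames(panelValues(p)))
    expect_true(any(pa$var == ycol & pa$lag == 1L))
    if (!any(pa$var == xcol & pa$lag == 2L)) removed <- removed + 1L
  }
  expect_gte(removed, 8L)
})

test_that("MCI statistics are invariant to affine rescaling of inputs", {
  sc <- twoLinkScenario(seed = 31, nWeeks = 500, buLag = 8L)
  p <- simulatePanel(sc)
  cfg <- pcmciConfig(tauMax = 10)
  vars <- colnames(panelValues(p))
  parents <- lapply(vars, function(v) pcConditionSelection(p, v, cfg))
  names(parents) <- vars
  m1 <- mciTestAll(p, parents, cfg)

  v2 <- panelValues(p)
  v2[, "Tmax"] <- 3.7 * v2[, "Tmax"] - 12
  v2[, "BA"] <- -0.5 * v2[, "BA"] + 4
  p2 <- firePanel(v2, variableGroups(p), weekOfYear = weekOfYear(p))
  m2 <- mciTestAll(p2, parents, cfg)
  expect_lt(max(abs(abs(m1$rho) - abs(m2$rho)), na.rm = TRUE), 1e-10)
})

test_that("two planted links into burned area are recovered with signs", {
  found <- 0L
  for (s in 1:5) {
    sc <- twoLinkScenario(seed = 40 + s)
    g <- runPCMCI(simulatePanel(sc), pcmciConfig(tauMax = 80))
    lk <- causalLinks(g)
    td <- lk[lk$source == "Tmax" & lk$target == "BA" & lk$lag == 1, ]
    bu <- lk[lk$source == "SWDI" & lk$target == "BA" & lk$lag == 60, ]
    if (nrow(td) == 1 && nrow(bu) == 1 && td$rho > 0 && bu$rho < 0)
      found <- found + 1L
  }
  expect_gte(found, 4L)
})

test_that("discovery is deterministic and audits retained links", {
  sc <- twoLinkScenario(seed = 51, nWeeks = 500, buLag = 10L)
  p <- simulatePanel(sc)
  cfg <- pcmciConfig(tauMax = 12)
  g1 <- runPCMCI(p, cfg)
  g2 <- runPCMCI(p, cfg)
  expect_identical(causalLinks(g1), causalLinks(g2))
  expect_identical(auditMatrices(g1)$rho, auditMatrices(g2)$rho)
  expect_true(validObject(g1))

  lk <- causalLinks(g1)
  expect_true(all(lk$pvalue <= cfg@alpha))
  # contemporaneous links only ever point at the target
  expect_true(all(lk$target[lk$lag == 0] == "BA"))
})

test_that("independent series at lag zero yield a mostly empty graph", {
  empty <- 0L
  for (s in 1:40) {
    p <- generateNullPanel(2, 200, seed = 300 + s)
    g <- runPCMCI(p, pcmciConfig(tauMax = 0, tauMin = 0))
    if (nrow(causalLinks(g)) == 0L) empty <- empty + 1L
  }
  # expected empty with probability ~0.95 per seed
  expect_gte(empty, 33L)
})

test_that("panels shorter than the lag window are rejected", {
  p <- generateNullPanel(3, 120, seed = 1)
  expect_error(runPCMCI(p, pcmciConfig(tauMax = 100)), "too short")
})
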