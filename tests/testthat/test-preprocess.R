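test_that("confidence masking uses a strict threshold", {
  out <- maskLowConfidence(c(5, 6, 7), c(69, 70, 100), threshold = 70)
  expect_true(is.na(out$values[1]))   # 69 < 70: masked
  expect_identical(out$values[2:3], c(6, 7))  # 70 passes, strict rule
  expect_identical(out$nMasked, 1L)

  x <- matrix(runif(20), 4, 5)
  all100 <- maskLowConfidence(x, matrix(100, 4, 5))
  expect_identical(all100$values, x)
  expect_identical(all100$nMasked, 0L)

  expect_error(maskLowConfidence(1:4, 1:5), "shape")
  expect_error(maskLowConfidence(1:4, 1:4, threshold = 150), "0, 100")
})

test_that("weekly aggregation follows the fixed 52-week calendar fold", {
  d <- seq(as.Date("2003-01-01"), by = "day", length.out = 7)
  expect_equal(aggregateToWeekly(rep(2, 7), d, "mean")$value, 2)
  expect_equal(aggregateToWeekly(c(0, 0, 1, 0, 2, 0, 0), d, "sum")$value, 3)

  # a full 365-day year folds to 52 weeks, the last covering 8 days
  yr <- seq(as.Date("2003-01-01"), as.Date("2003-12-31"), by = "day")
  out <- aggregateToWeekly(rep(1, 365), yr, "sum")
  expect_identical(nrow(out), 52L)
  expect_identical(out$week_of_year, 1:52)
  # brute-force day enumeration: week w covers days 7(w-1)+1..7w, week 52
  # absorbs day 365
  daysPerWeek <- table(pmin((seq_len(365) - 1) %/% 7 + 1, 52))
  expect_identical(out$value, as.numeric(daysPerWeek))
  expect_identical(out$value[52], 8)

  # missing-day policy: dropped from means, propagated through sums
  d2 <- seq(as.Date("2003-01-01"), by = "day", length.out = 7)
  v <- c(1, NA, 3, NA, NA, NA, NA)
  expect_equal(aggregateToWeekly(v, d2, "mean")$value, 2)
  expect_true(is.na(aggregateToWeekly(v, d2, "sum")$value))
  expect_true(is.na(aggregateToWeekly(rep(NA_real_, 7), d2,
                                      "mean")$value))
})

test_that("burned-area log transform is zero-preserving and de-skewing", {
  expect_identical(logTransformBA(0), 0)
  expect_equal(logTransformBA(exp(1) - 1), 1, tolerance = 1e-12)
  expect_error(logTransformBA(-1), "non-negative")

  sc <- oneLinkScenario(nWeeks = 2000, seed = 21,
                        baZeroInflation = 0.3, baSkewTransform = TRUE)
  ba <- panelValues(simulatePanel(sc))[, "BA"]
  nz <- ba[ba > 0]
  expect_lt(abs(sampleSkewness(logTransformBA(nz))),
            abs(sampleSkewness(nz)))
})

test_that("linear detrending recovers exact and noisy trends", {
  t <- 1:200
  out <- detrendLinear(3 + 0.01 * t)
  expect_lt(max(abs(out$values)), 1e-10)
  expect_equal(out$slope, 0.01, tolerance = 1e-10)
  expect_equal(out$intercept, 3, tolerance = 1e-8)

  cst <- detrendLinear(rep(5, 150))
  expect_lt(max(abs(cst$values)), 1e-10)
  expect_equal(cst$slope, 0, tolerance = 1e-12)

  set.seed(4)
  n <- 936
  y <- 1 + 0.02 * (1:n) + rnorm(n)
  fit <- detrendLinear(y)
  se <- summary(lm(y ~ I(1:n)))$coefficients[2, 2]  # OLS oracle
  expect_lt(abs(fit$slope - 0.02), 3 * se)
  expect_lt(abs(mean(fit$values)), 1e-10)

  expect_error(detrendLinear(rep(NA_real_, 200)), "non-missing")
  expect_error(detrendLinear(rnorm(50)), "non-missing")
})

test_that("seasonal-cycle removal zeroes pure cycles and is idempotent", {
  woy <- rep(1:52, 18)
  cyc <- rep(sin(2 * pi * (1:52) / 52), 18)
  out <- removeSeasonalCycle(cyc, woy)
  expect_lt(max(abs(out$values)), 1e-10)
  expect_lt(max(abs(removeSeasonalCycle(rep(7, 104),
                                        rep(1:52, 2))$values)), 1e-10)

  set.seed(8)
  x <- cyc + 0.01 * seq_along(cyc) + rnorm(length(cyc))
  a1 <- removeSeasonalCycle(detrendLinear(x)$values, woy)
  a2 <- removeSeasonalCycle(a1$values, woy)
  expect_lt(max(abs(a2$values - a1$values)), 1e-10)
  # anomalies are white at the seasonal lag
  n <- length(a1$values)
  r52 <- cor(a1$values[1:(n - 52)], a1$values[53:n])
  expect_lt(abs(r52), 3 / sqrt(n))

  expect_error(removeSeasonalCycle(c(1, NA), c(1, 2)), "zero observations")
})

test_that("detrend and deseasonalize commute with scalar rescaling", {
  set.seed(12)
  woy <- rep(1:52, 4)
  x <- rnorm(208) + rep(cos(2 * pi * (1:52) / 52), 4)
  for (a in c(-2, 0.5, 10)) {
    expect_lt(max(abs(detrendLinear(a * x)$values -
                        a * detrendLinear(x)$values)), 1e-10)
    expect_lt(max(abs(removeSeasonalCycle(a * x, woy)$values -
                        a * removeSeasonalCycle(x, woy)$values)), 1e-10)
  }
})

test_that("joint climatology fit annihilates periodic-plus-linear input", {
  woy <- rep(1:52, 18)
  t <- seq_along(woy)
  x <- 5 + 0.02 * t + rep(sin(2 * pi * (1:52) / 52), 18)
  fc <- fitClimatology(x, woy)
  expect_lt(max(abs(fc$values)), 1e-8)
  expect_equal(fc$model@slope, 0.02, tolerance = 1e-6)
  # residuals per week of year average exactly to zero
  expect_lt(max(abs(tapply(fc$values, woy, mean))), 1e-10)
  # missing entries stay missing, rest as without them
  x2 <- x; x2[c(10, 400)] <- NA
  fc2 <- fitClimatology(x2, woy)
  expect_true(all(is.na(fc2$values[c(10, 400)])))
  expect_lt(max(abs(fc2$values), na.rm = TRUE), 1e-8)
})

test_that("the panel pipeline applies and records the fixed stage order", {
  sc <- oneLinkScenario(nWeeks = 520, seed = 2, baZeroInflation = 0.3,
                        baSkewTransform = TRUE)
  p <- simulatePanel(sc)
  out <- preprocessPanel(p)
  expect_identical(panelMetadata(out$panel)$pipeline,
                   c("log", "detrend", "deseasonalize"))
  v <- panelValues(out$panel)
  woy <- weekOfYear(out$panel)
  # anomalies average to zero overall and per week of year
  for (j in colnames(v)) {
    expect_lt(abs(mean(v[, j])), 1e-9)
    expect_lt(max(abs(tapply(v[, j], woy, mean))), 1e-9)
  }
  expect_s4_class(out$climatology[["BA"]], "ClimatologyModel")
})
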