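test_that("noiseless sinusoids are recovered exactly", {
  y <- 2 * cos(2 * pi * (1:30) / 6) + 5      # period 6 steps = 24 h
  f <- fitSinusoid(countSeries4h(y))
  cf <- f@coefficients
  expect_equal(unname(cf["a1"]), 2, tolerance = 1e-6)
  expect_equal(unname(cf["a2"]), 0, tolerance = 1e-6)
  expect_equal(unname(cf["a3"]), 5, tolerance = 1e-6)
  expect_equal(fittedPeriod(f), 24, tolerance = 1e-6)
  expect_true(isConverged(f))
  expect_equal(rhythmAmplitude(f), 2, tolerance = 1e-6)
  ## observed = fitted + residuals on non-missing slots
  expect_equal(fitted(f) + residuals(f), y, tolerance = 1e-9)
})

test_that("a constant series shows no significant rhythm", {
  f <- suppressWarnings(fitSinusoid(countSeries4h(rep(5, 30))))
  expect_lt(rhythmAmplitude(f), 1e-6)
  p <- suppressWarnings(periodSignificance(f))
  expect_true(is.na(p) || p > 0.05)
})

test_that("fixed-period fits equal closed-form harmonic regression", {
  set.seed(11)
  y <- 3 * cos(2 * pi * (1:30) / 6 - 1) + 6 + rnorm(30, 0, 0.8)
  f <- fitSinusoid(countSeries4h(y), fixPeriodH = 24)
  tt <- 1:30
  X <- cbind(cos(2 * pi * tt / 6), sin(2 * pi * tt / 6), 1)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(f@coefficients[c("a1", "a2", "a3")]),
               as.numeric(beta), tolerance = 1e-8)
  expect_true(f@periodFixed)

  ## with trend term
  y2 <- y + 0.1 * tt
  f2 <- fitSinusoid(countSeries4h(y2), withTrend = TRUE, fixPeriodH = 24)
  X2 <- cbind(X, tt)
  beta2 <- solve(crossprod(X2), crossprod(X2, y2))
  expect_equal(unname(f2@coefficients[c("a1", "a2", "a3", "a5")]),
               as.numeric(beta2), tolerance = 1e-8)

  ## the free-period optimum cannot be worse than the fixed-24-h fit
  free <- fitSinusoid(countSeries4h(y))
  expect_lte(sum(residuals(free)^2), sum(residuals(f)^2) + 1e-10)
})

test_that("fits shift with an additive constant only through the intercept", {
  set.seed(12)
  y <- 2.5 * cos(2 * pi * (1:30) / 6 - 0.7) + 7 + rnorm(30, 0, 0.5)
  f1 <- fitSinusoid(countSeries4h(y))
  f2 <- fitSinusoid(countSeries4h(y + 10))
  expect_equal(unname(f2@coefficients["a3"]),
               unname(f1@coefficients["a3"]) + 10, tolerance = 1e-4)
  expect_equal(unname(f2@coefficients[c("a1", "a2", "a4")]),
               unname(f1@coefficients[c("a1", "a2", "a4")]),
               tolerance = 1e-4)
})

test_that("missing slots keep their calendar position in the fit", {
  y <- 2 * cos(2 * pi * (1:30) / 6) + 5
  y[c(4, 9, 17)] <- NA
  f <- fitSinusoid(countSeries4h(y))
  expect_equal(fittedPeriod(f), 24, tolerance = 1e-5)
  expect_equal(f@tIndex, setdiff(1:30, c(4, 9, 17)))
  expect_equal(length(residuals(f)), 27)
})

test_that("period recovery from Poisson-noise rhythms is accurate", {
  errs <- vapply(1:60, function(s)
    abs(fittedPeriod(suppressWarnings(fitSinusoid(rhythmCounts(s)))) - 24),
    numeric(1))
  expect_lte(median(errs), 1.5)
})

test_that("period significance behaves at the zero-error limit", {
  f <- suppressWarnings(fitSinusoid(countSeries4h(
    2 * cos(2 * pi * (1:30) / 6) + 5), fixPeriodH = 24))
  expect_error(periodSignificance(f), "fixed")

  strong <- suppressWarnings(fitSinusoid(rhythmCounts(1)))
  p <- periodSignificance(strong)
  expect_lt(p, 0.001)
  ## se -> 0 drives p -> 0
  strong@se["a4"] <- 0
  expect_equal(periodSignificance(strong), 0)
})

test_that("trend model recovers a linear drift in the rate", {
  s <- rhythmCounts(7, amplitude = 6, mesorLevel = 6, trendSlope = 0.3)
  f <- suppressWarnings(fitSinusoid(s, withTrend = TRUE))
  expect_true("a5" %in% names(f@coefficients))
  expect_gt(unname(f@coefficients["a5"]), 0)
  expect_equal(unname(f@coefficients["a5"]), 0.3, tolerance = 0.2)
})

test_that("residual diagnostics conserve counts and center residuals", {
  y <- 2 * cos(2 * pi * (1:30) / 6) + 5
  f <- fitSinusoid(countSeries4h(y))
  d <- residualDiagnostics(f)
  expect_true(all(abs(d$pairs$residual) < 1e-8))
  expect_equal(sum(d$counts), 30)
  expect_equal(length(d$counts), 1)           # perfect fit: one bin

  set.seed(5)
  f2 <- fitSinusoid(countSeries4h(y + rnorm(30)))
  d2 <- residualDiagnostics(f2, bins = 7)
  expect_equal(sum(d2$counts), 30)
  expect_equal(length(d2$counts), 7)
  expect_lt(abs(mean(d2$pairs$residual)), 0.1)  # ~0 with intercept
})

test_that("an out-of-band initial period is rejected and edges warn", {
  s <- countSeries4h(2 * cos(2 * pi * (1:30) / 6) + 5)
  expect_error(fitSinusoid(s, initPeriodH = 40), "within")
  ## data with a 16.7-h period pushes the fit toward the band edge
  y <- 3 * cos(2 * pi * (1:30) / 4) + 6       # 16-h rhythm at band edge
  expect_warning(fitSinusoid(countSeries4h(y), initPeriodH = 17,
                             periodBandH = c(16, 18)), "edge|band")
})

test_that("fit summaries export one row per series", {
  fits <- list(a = suppressWarnings(fitSinusoid(rhythmCounts(3))),
               b = suppressWarnings(fitSinusoid(rhythmCounts(4))))
  tab <- exportFitTable(fits)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("period_h", "period_p", "amplitude", "converged")
                  %in% names(tab)))
  tmp <- tempfile(fileext = ".tsv")
  exportFitTable(fits, tmp)
  expect_equal(nrow(read.delim(tmp)), 2)
})
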