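test_that("CCF critical values reproduce the analytic band", {
  expect_equal(round(ccfCriticalValue(30, 0.05), 2), 0.36)
  expect_equal(round(ccfCriticalValue(31, 0.05), 2), 0.35)
  expect_equal(round(ccfCriticalValue(30, 0.10), 2), 0.30)
  expect_equal(ccfCriticalValue(100, 0.05), qnorm(0.975) / 10,
               tolerance = 1e-12)
})

test_that("the CCF matches Pearson at lag 0 and the standard estimator", {
  set.seed(14)
  x <- envSeries4h(rnorm(30)); y <- countSeries4h(rpois(30, 5))
  cr <- crossCorrelation(x, y, maxLagSteps = 6)
  ## lag 0 equals the Pearson correlation of the aligned pair
  expect_equal(ccfValues(cr)[1],
               cor(seriesValues(x), seriesValues(y)), tolerance = 1e-12)
  ## all lags equal the standard sample CCF (stats::ccf convention)
  ref <- ccf(seriesValues(x), seriesValues(y), lag.max = 6,
             plot = FALSE, demean = TRUE)
  refPos <- ref$acf[ref$lag <= 0]             # env leading = negative side
  expect_equal(ccfValues(cr), rev(as.numeric(refPos)), tolerance = 1e-10)
  expect_equal(ccfLags(cr), seq(0, 24, by = 4))
})

test_that("a series against itself is perfectly correlated at lag 0", {
  set.seed(15)
  v <- rpois(30, 6)
  cr <- crossCorrelation(envSeries4h(v), countSeries4h(v))
  expect_equal(ccfValues(cr)[1], 1.0, tolerance = 1e-12)
})

test_that("a half-period shift flips the CCF sign between lags 0 and 12 h", {
  tH <- (0:29) * 4
  env <- envSeries4h(cos(2 * pi * tH / 24))
  bio <- countSeries4h(5 + 4 * cos(2 * pi * (tH - 12) / 24))
  cr <- crossCorrelation(env, bio)
  v <- ccfValues(cr); lag <- ccfLags(cr)
  expect_equal(lag[which.min(v)], 0)
  expect_equal(lag[which.max(v)], 12)
})

test_that("degenerate CCF inputs are rejected", {
  expect_error(crossCorrelation(envSeries4h(rep(1, 30)),
                                countSeries4h(rpois(30, 5))),
               "zero-variance")
  expect_error(crossCorrelation(envSeries4h(rnorm(8)),
                                countSeries4h(rpois(8, 5))), "common")
})

test_that("lagging a series shortens and composes correctly", {
  s <- countSeries4h(1:30)
  l12 <- lagSeries(s, 12)
  expect_equal(length(seriesValues(l12)), 27)
  expect_equal(seriesValues(l12), 4:30)
  expect_identical(lagSeries(s, 0), s)
  expect_equal(seriesValues(lagSeries(lagSeries(s, 4), 4)),
               seriesValues(lagSeries(s, 8)))
  expect_error(lagSeries(s, 6), "multiple")
})

test_that("RDA recovers a perfectly constrained response", {
  set.seed(16)
  x <- rnorm(20)
  Y <- outer(x, c(1, 2, -1))                   # exactly linear in x
  X <- cbind(driver = x, noise = rnorm(20))
  r <- rdaFit(Y, X, lagHours = 0)
  expect_equal(sum(propExplained(r)), 1, tolerance = 1e-10)
  expect_equal(propExplained(r)[1], 1, tolerance = 1e-10)
  expect_equal(abs(biplotScores(r)["driver", 1]), 1, tolerance = 1e-8)
  ## canonical sign: the dominant predictor loads positively
  expect_gt(biplotScores(r)["driver", 1], 0)
})

test_that("a response orthogonal to the predictors explains nothing", {
  set.seed(17)
  X <- matrix(rnorm(60), 20, 3)
  Y0 <- matrix(rnorm(40), 20, 2)
  ## project out the predictor space (plus intercept)
  Q <- qr.Q(qr(cbind(1, scale(X))))
  Y <- Y0 - Q %*% crossprod(Q, Y0)
  r <- rdaFit(Y, X, lagHours = 0)
  expect_lt(max(rdaEigenvalues(r)), 1e-20)
})

test_that("RDA equals the brute-force regression + eigendecomposition", {
  set.seed(18)
  Y <- matrix(rnorm(18, sd = 2), 6, 3)
  X <- matrix(rnorm(18), 6, 3)
  colnames(Y) <- paste0("t", 1:3); colnames(X) <- paste0("v", 1:3)
  r <- rdaFit(Y, X, lagHours = 0)
  o <- rdaOracle(Y, X)
  expect_equal(rdaEigenvalues(r), o$eigenvalues, tolerance = 1e-8)
  ## species directions and env correlations up to axis sign
  expect_equal_upto_sign(
    sweep(speciesScores(r), 2, sqrt(rdaEigenvalues(r)), "/"), o$V, 1e-7)
  expect_equal_upto_sign(biplotScores(r), o$env, 1e-8)
  ## variance conservation: sum of eigenvalues = fitted variance
  expect_equal(sum(rdaEigenvalues(r)), o$totalFitted, tolerance = 1e-10)
})

test_that("RDA agrees with vegan on the constrained eigenvalues", {
  skip_if_not_installed("vegan")
  set.seed(19)
  Y <- matrix(rpois(90, 6), 30, 3)
  X <- matrix(rnorm(150), 30, 5)
  r <- rdaFit(Y, X, lagHours = 0)
  veg <- vegan::rda(Y ~ ., data = as.data.frame(scale(X)))
  expect_equal(unname(rdaEigenvalues(r)),
               unname(veg$CCA$eig)[seq_along(rdaEigenvalues(r))],
               tolerance = 1e-8)
})

test_that("RDA is invariant to invertible recombinations of predictors", {
  set.seed(20)
  Y <- matrix(rnorm(60), 20, 3)
  X <- matrix(rnorm(60), 20, 3)
  A <- matrix(c(2, 0.3, 0, -1, 1, 0.5, 0.2, 0, 1), 3, 3)
  r1 <- rdaFit(Y, X, lagHours = 0)
  r2 <- rdaFit(Y, X %*% A, lagHours = 0)
  expect_equal(rdaEigenvalues(r1), rdaEigenvalues(r2), tolerance = 1e-8)
  expect_equal_upto_sign(siteScores(r1), siteScores(r2), 1e-6)
})

test_that("collinear predictors are dropped with a warning", {
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  X <- cbind(X, X[, 1] * 2)
  colnames(X) <- c("a", "b", "a2")
  Y <- matrix(rnorm(40), 20, 2)
  expect_warning(r <- rdaFit(Y, X, lagHours = 0), "collinear")
  expect_equal(r@dropped, "a2")
})

test_that("RDA score tables are complete and deterministic", {
  set.seed(22)
  Y <- matrix(rpois(60, 4), 20, 3,
              dimnames = list(NULL, c("sp1", "sp2", "sp3")))
  X <- matrix(rnorm(80), 20, 4,
              dimnames = list(NULL, c("flow", "temp", "oxy", "chl")))
  r <- rdaFit(Y, X)
  tab <- rdaReport(r)
  expect_equal(nrow(tab), 3 + 4)               # taxa + variables
  expect_setequal(unique(tab$type), c("species", "environment"))
  f1 <- tempfile(); f2 <- tempfile()
  rdaReport(rdaFit(Y, X), f1); rdaReport(rdaFit(Y, X), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("lagged coupling is recovered by the CCF argmax", {
  hits <- vapply(1:50, function(s) {
    cc <- coupledCounts(s)
    cr <- crossCorrelation(cc$env4, cc$bio)
    ccfLags(cr)[which.max(ccfValues(cr))] == 12
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
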