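## Shared fixtures and independent oracles, built in code.

## 4-h grid starting at local midnight
grid4h <- function(n, start = "2013-06-01 00:00:00") {
  seq(as.POSIXct(start, tz = localTimezone()), by = 4 * 3600,
      length.out = n)
}

grid1h <- function(n, start = "2013-06-01 00:00:00") {
  seq(as.POSIXct(start, tz = localTimezone()), by = 3600, length.out = n)
}

countSeries4h <- function(values, taxon = "taxon1") {
  CountSeries(taxon, grid4h(length(values)), values)
}

envSeries1h <- function(values, variable = "var") {
  EnvSeries(variable, grid1h(length(values)), values)
}

envSeries4h <- function(values, variable = "var") {
  EnvSeries(variable, grid4h(length(values)), values)
}

## Lomb-Scargle oracle: per-frequency least-squares fit of a sinusoid to
## the mean-subtracted series; power = SSE reduction / (2 * sample var)
lsOracle <- function(tH, y, freq) {
  yc <- y - mean(y)
  sse0 <- sum(yc^2)
  vapply(freq, function(f) {
    X <- cbind(cos(2 * pi * f * tH), sin(2 * pi * f * tH))
    r <- lm.fit(X, yc)$residuals
    (sse0 - sum(r^2)) / (2 * var(y))
  }, numeric(1))
}

## RDA oracle: explicit multivariate regression + eigendecomposition of
## the fitted-value covariance
rdaOracle <- function(Y, X) {
  Y <- as.matrix(Y); X <- scale(as.matrix(X))
  Yc <- scale(Y, scale = FALSE)
  B <- solve(crossprod(X), crossprod(X, Yc))
  Yhat <- X %*% B
  eg <- eigen(cov(Yhat), symmetric = TRUE)
  k <- min(ncol(Y), qr(X)$rank)
  lambda <- pmax(eg$values[seq_len(k)], 0)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  sites <- Yhat %*% V
  env <- suppressWarnings(cor(X, sites))
  env[is.na(env)] <- 0
  list(eigenvalues = lambda, V = V, sites = sites, env = env,
       totalFitted = sum(apply(Yhat, 2, var)))
}

## compare two matrices column-by-column up to sign
expect_equal_upto_sign <- function(a, b, tol = 1e-8) {
  a <- unname(as.matrix(a)); b <- unname(as.matrix(b))
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    d <- min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
    expect_lt(d, tol)
  }
}

## Poisson count series with a diel rhythm on the default 5-day design
rhythmCounts <- function(seed, amplitude = 6, mesorLevel = 6,
                         acrophaseH = 11, periodH = 24, trendSlope = 0) {
  rec <- genCountSeries(
    rhythmSpec(periodH, amplitude, mesorLevel, acrophaseH, trendSlope),
    samplingSpec(rngSeed = seed))
  pairAndNormalize(rec, "taxon1")
}

## driver-coupled counts: no intrinsic rhythm, rate = mesor + gain * lagged
## cosine driver; gain chosen for a target correlation r given
## var(driver) = 1/2 and Poisson noise variance ~ mesor/2
coupledCounts <- function(seed, lagH = 12, r = 0.6, mesorLevel = 6) {
  gain <- sqrt(r^2 * mesorLevel / 2 / (0.5 * (1 - r^2)))
  driver <- genEnvSeries(
    envDriverSpec("driver",
                  list(list(periodH = 24, amplitude = 1, phaseRad = 0))),
    samplingSpec(rngSeed = seed))
  rec <- genCountSeries(rhythmSpec(24, 0, mesorLevel, 0),
                        samplingSpec(rngSeed = seed),
                        couplingSpec("driver", lagH = lagH, gain = gain),
                        driver)
  list(bio = pairAndNormalize(rec, "taxon1"),
       env4 = average4h(driver))
}
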