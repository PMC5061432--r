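## Lagged biology-environment association: positive-lag cross-correlation
## with analytic white-noise bounds, and redundancy analysis of the
## lagged species matrix on z-scored environmental predictors.

#' Analytic white-noise critical value for the CCF
#'
#' `z_(1-alpha/2) / sqrt(n)` -- the band outside which a sample
#' cross-correlation of two independent white-noise series falls with
#' probability `alpha` per lag. Rounded only at display time.
#'
#' @param n Paired sample size (>= 2).
#' @param alpha Two-sided significance level.
#' @return The critical value.
#' @export
#' @examples
#' round(ccfCriticalValue(30), 2)         # 0.36
#' round(ccfCriticalValue(30, 0.10), 2)   # 0.30
ccfCriticalValue <- function(n, alpha = 0.05) {
  stopifnot(n >= 2)
  qnorm(1 - alpha / 2) / sqrt(n)
}

#' Cross-correlation of an environmental and a biological series
#'
#' Sample CCF at non-negative lags `k = 0..maxLagSteps` (environment
#' leading):
#' `ccf(k) = sum_t (x_t - xbar)(y_(t+k) - ybar) / (n * s_x * s_y)`,
#' with means and standard deviations fixed at their full-series values
#' and divisor `n` -- the convention under which `+/- z/sqrt(n)` is the
#' white-noise band. Only non-negative lags are computed: abundances do
#' not drive the environment. Missing slots are dropped pairwise.
#'
#' @param env A 4-hourly [EnvSeries-class] (x, leading).
#' @param bio A [CountSeries-class] (y, lagging).
#' @param maxLagSteps Maximum lag in 4-h steps (default 6 = 24 h).
#' @return A [CCFResult-class]; lags are reported in hours.
#' @export
crossCorrelation <- function(env, bio, maxLagSteps = 6) {
  te <- as.numeric(seriesTimes(env)); tb <- as.numeric(seriesTimes(bio))
  common <- intersect(te, tb)
  if (length(common) < maxLagSteps + 10)
    stop("need at least ", maxLagSteps + 10, " common slots")
  common <- sort(common)
  x <- seriesValues(env)[match(common, te)]
  y <- seriesValues(bio)[match(common, tb)]
  ok <- !is.na(x) & !is.na(y)
  x[!ok] <- NA; y[!ok] <- NA
  n <- sum(ok)
  if (n < maxLagSteps + 10) stop("too few complete pairs")
  xb <- mean(x, na.rm = TRUE); yb <- mean(y, na.rm = TRUE)
  sx <- sqrt(sum((x[ok] - xb)^2) / n)       # divisor n, fixed overall
  sy <- sqrt(sum((y[ok] - yb)^2) / n)
  if (sx == 0 || sy == 0) stop("zero-variance input")
  m <- length(common)
  cc <- vapply(0:maxLagSteps, function(k) {
    i <- seq_len(m - k)
    sum((x[i] - xb) * (y[i + k] - yb), na.rm = TRUE) / (n * sx * sy)
  }, numeric(1))
  new("CCFResult", taxon = taxonName(bio), envVariable = varName(env),
      lagsHours = (0:maxLagSteps) * 4, ccf = cc, n = as.integer(n),
      crit05 = ccfCriticalValue(n, 0.05),
      crit10 = ccfCriticalValue(n, 0.10))
}

#' Shift a biological series backward by a lag
#'
#' Aligns biology at `t + lag` against environment at `t`: the returned
#' series holds, at each retained timestamp, the biological value
#' observed `lagH` hours later, shortened by `lagH/4` slots.
#'
#' @param bio A [CountSeries-class].
#' @param lagH Lag in hours; must be a non-negative multiple of 4.
#' @return A [CountSeries-class] of length `n - lagH/4`.
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2013-06-01", tz = localTimezone()),
#'           by = 4 * 3600, length.out = 30)
#' length(seriesValues(lagSeries(CountSeries("x", ts, 1:30), 12)))  # 27
lagSeries <- function(bio, lagH) {
  if (lagH < 0 || abs(lagH %% 4) > 1e-9)
    stop("lag must be a non-negative multiple of the 4-h grid")
  k <- as.integer(round(lagH / 4))
  v <- seriesValues(bio); ts <- seriesTimes(bio)
  if (k == 0) return(bio)
  if (k >= length(v)) stop("lag exceeds series length")
  n <- length(v)
  CountSeries(taxonName(bio), ts[seq_len(n - k)], v[(k + 1):n])
}

#' Redundancy analysis of species abundances on environmental predictors
#'
#' Multivariate linear regression of the column-centered response matrix
#' on z-scored predictors, followed by an eigendecomposition of the
#' fitted-value covariance (PCA of the constrained variation). Collinear
#' predictors are dropped with a warning. Scores follow the
#' correlation-biplot (scaling 2) convention: species scores are
#' response eigenvectors weighted by `sqrt(eigenvalue)`, site scores are
#' standardized, and predictor biplot scores are the correlations of
#' each predictor with each axis's site scores (range -1 to 1). Axis
#' signs are canonicalized by forcing the predictor with the largest
#' absolute loading positive on each axis.
#'
#' @param bioMatrix Numeric matrix, slots x taxa (biology already lagged
#'   via [lagSeries()] as appropriate).
#' @param envMatrix Numeric matrix, slots x variables; z-scored
#'   internally (idempotent for pre-scaled input).
#' @param lagHours Lag already applied to the biology, recorded in the
#'   result (default 12).
#' @return An [RDAResult-class].
#' @export
rdaFit <- function(bioMatrix, envMatrix, lagHours = 12) {
  Y <- as.matrix(bioMatrix); X <- as.matrix(envMatrix)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("taxon", seq_len(ncol(Y)))
  if (is.null(colnames(X))) colnames(X) <- paste0("var", seq_len(ncol(X)))
  cc <- complete.cases(Y) & complete.cases(X)
  Y <- Y[cc, , drop = FALSE]; X <- X[cc, , drop = FALSE]
  n <- nrow(Y)
  if (n <= ncol(X)) stop("need more complete slots than predictors")

  ## z-score predictors (sample sd); constant columns are degenerate
  csd <- apply(X, 2, sd)
  if (any(csd == 0)) stop("constant predictor(s): ",
                          paste(colnames(X)[csd == 0], collapse = ", "))
  X <- scale(X)

  dropped <- character()
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping collinear predictor(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }

  Yc <- scale(Y, scale = FALSE)
  Yhat <- qr.fitted(qrX, Yc)
  sv <- svd(Yhat / sqrt(n - 1))
  lambda <- sv$d^2
  nAxes <- min(qrX$rank, ncol(Y))
  keepAx <- seq_len(nAxes)
  lambda <- lambda[keepAx]
  V <- sv$v[, keepAx, drop = FALSE]               # species eigenvectors
  U <- sv$u[, keepAx, drop = FALSE]               # standardized sites

  totVar <- sum(apply(Yc, 2, var))
  axNames <- paste0("RDA", keepAx)

  siteRaw <- Yhat %*% V                            # per-axis var = lambda
  envScores <- suppressWarnings(cor(X, siteRaw))
  envScores[is.na(envScores)] <- 0                 # axes with ~0 variance

  ## canonicalize axis signs: largest |env loading| positive
  for (j in keepAx) {
    i <- which.max(abs(envScores[, j]))
    if (envScores[i, j] < 0) {
      V[, j] <- -V[, j]; U[, j] <- -U[, j]
      siteRaw[, j] <- -siteRaw[, j]; envScores[, j] <- -envScores[, j]
    }
  }
  species <- V %*% diag(sqrt(lambda), nAxes)
  dimnames(species) <- list(colnames(Y), axNames)
  dimnames(U) <- list(rownames(Y), axNames)
  colnames(envScores) <- axNames

  new("RDAResult", eigenvalues = lambda,
      propExplained = lambda / totVar, siteScores = U,
      speciesScores = species, envScores = envScores,
      lagHours = lagHours, totalVariance = totVar, dropped = dropped)
}

#' Flat score table for an RDA result
#'
#' Species and environmental-variable scores on the first two constrained
#' axes, one row per entity.
#'
#' @param res An [RDAResult-class].
#' @param file Optional TSV path.
#' @return The score data frame (invisibly if `file` is given).
#' @export
rdaReport <- function(res, file = NULL) {
  nAx <- min(2L, length(res@eigenvalues))
  pad <- function(m) {
    out <- matrix(NA_real_, nrow(m), 2,
                  dimnames = list(rownames(m), c("RDA1", "RDA2")))
    out[, seq_len(nAx)] <- m[, seq_len(nAx)]
    out
  }
  sp <- pad(res@speciesScores); en <- pad(res@envScores)
  out <- data.frame(
    entity = c(rownames(sp), rownames(en)),
    type = c(rep("species", nrow(sp)), rep("environment", nrow(en))),
    RDA1 = c(sp[, 1], en[, 1]), RDA2 = c(sp[, 2], en[, 2]),
    row.names = NULL)
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export a CCF result as TSV
#'
#' @param res A [CCFResult-class].
#' @param file TSV path; columns `lag_h`, `ccf`, `crit05`, `crit10`.
#' @return Invisibly, `file`.
#' @export
exportCCF <- function(res, file) {
  write.table(as.data.frame(res), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
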