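## Free-period sinusoidal least-squares models for 4-hourly count series.
##
## Model: y(t) = a1*cos(2*pi*t/a4) + a2*sin(2*pi*t/a4) + a3 [+ a5*t],
## t = 1..n the integer slot index (4-h steps). a4 is the period in steps
## and is reported in hours (a4 * 4). The trend term a5*t is optional and
## meant for series riding a lower-frequency (spring-tide) signal.

harmonicDesign <- function(tt, periodSteps, withTrend) {
  X <- cbind(a1 = cos(2 * pi * tt / periodSteps),
             a2 = sin(2 * pi * tt / periodSteps),
             a3 = rep(1, length(tt)))
  if (withTrend) X <- cbind(X, a5 = tt)
  X
}

## closed-form least squares at a fixed period; returns coef/se/t/p
harmonicRegression <- function(y, tt, periodSteps, withTrend,
                               stats = TRUE) {
  X <- harmonicDesign(tt, periodSteps, withTrend)
  fit <- lm(y ~ X - 1)
  cf <- coef(fit); names(cf) <- colnames(X)
  sm <- NULL
  if (stats) {
    sm <- summary(fit)$coefficients
    rownames(sm) <- colnames(X)
  }
  list(coef = cf, table = sm, fitted = as.numeric(X %*% cf),
       residuals = as.numeric(y - X %*% cf),
       df = length(y) - ncol(X))
}

#' Fit a free-period sinusoid to a count series
#'
#' Levenberg-Marquardt least squares over `(a1, a2, a3, a4[, a5])` with
#' `t = 1..n` in 4-h steps. The period `a4` is initialized at
#' `initPeriodH` and constrained to `periodBandH` (default 16-32 h, the
#' diel branch; keeps the optimizer off tidal harmonics). Starting values
#' for `a1, a2, a3` come from harmonic regression at the initial period
#' and `a5` from a linear pre-fit. Standard errors derive from the
#' Jacobian at the optimum. Non-convergence yields a flagged result, not
#' an error; a period pinned at a band edge raises a warning.
#'
#' With `fixPeriodH` set, the period is held fixed and the fit reduces to
#' closed-form harmonic regression (useful as a linear-algebra oracle and
#' for scanning candidate periods).
#'
#' @param series A [CountSeries-class] with at least 8 non-missing slots.
#' @param withTrend Include the linear trend term `a5*t`.
#' @param initPeriodH Initial period, hours (default 24).
#' @param periodBandH Search band for the period, hours.
#' @param fixPeriodH If non-`NULL`, fit with this period held fixed.
#' @return A [SinusoidFit-class].
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2013-06-01", tz = localTimezone()),
#'           by = 4 * 3600, length.out = 30)
#' y <- 2 * cos(2 * pi * (1:30) / 6) + 5
#' fitSinusoid(CountSeries("toy", ts, y))
fitSinusoid <- function(series, withTrend = FALSE, initPeriodH = 24,
                        periodBandH = c(16, 32), fixPeriodH = NULL) {
  v <- seriesValues(series)
  obs <- which(!is.na(v))
  if (length(obs) < 8) stop("need at least 8 non-missing slots")
  intH <- if (length(seriesTimes(series)) >= 2)
    gridSpacingHours(seriesTimes(series)) else 4
  tt <- as.numeric(obs)                     # calendar slot index
  y <- v[obs]
  nobs <- length(y)

  if (!is.null(fixPeriodH)) {
    hr <- harmonicRegression(y, tt, fixPeriodH / intH, withTrend)
    cf <- c(hr$coef[c("a1", "a2", "a3")], a4 = fixPeriodH / intH)
    if (withTrend) cf <- c(cf, a5 = unname(hr$coef["a5"]))
    nmLin <- setdiff(names(cf), "a4")
    se <- tv <- pv <- setNames(rep(NA_real_, length(cf)), names(cf))
    se[nmLin] <- hr$table[nmLin, "Std. Error"]
    tv[nmLin] <- hr$table[nmLin, "t value"]
    pv[nmLin] <- hr$table[nmLin, "Pr(>|t|)"]
    return(newSinusoidFit(series, cf, se, tv, pv, hr$fitted,
                          hr$residuals, as.integer(obs),
                          as.integer(hr$df), TRUE, withTrend, TRUE, intH,
                          "fixed-period harmonic regression"))
  }

  if (initPeriodH < periodBandH[1] || initPeriodH > periodBandH[2])
    stop("initPeriodH must lie within periodBandH")

  ## starting values
  a5start <- 0
  yDet <- y
  if (withTrend) {
    a5start <- unname(coef(lm(y ~ tt))[2])
    yDet <- y - a5start * tt
  }
  hr0 <- harmonicRegression(yDet, tt, initPeriodH / intH, FALSE,
                            stats = FALSE)
  start <- list(a1 = unname(hr0$coef["a1"]), a2 = unname(hr0$coef["a2"]),
                a3 = unname(hr0$coef["a3"]), a4 = initPeriodH / intH)
  if (withTrend) start$a5 <- a5start
  k <- length(start)

  ## if the starting values already fit exactly (noiseless data at the
  ## initial period), the optimizer's gradient is singular there; the
  ## start IS the optimum
  X0 <- harmonicDesign(tt, start$a4, withTrend)
  cf0 <- unlist(start)
  res0 <- as.numeric(y - X0 %*% cf0[names(cf0) != "a4"])
  if (sum(res0^2) <= 1e-16 * max(1, sum((y - mean(y))^2))) {
    se <- setNames(rep(0, k), names(cf0))
    tv <- setNames(rep(NA_real_, k), names(cf0))
    pv <- setNames(rep(0, k), names(cf0))
    if (sqrt(cf0["a1"]^2 + cf0["a2"]^2) < 1e-12 * max(1, abs(cf0["a3"]))) {
      ## constant series: no rhythm, period unidentifiable
      se["a4"] <- NA_real_
      pv["a4"] <- NA_real_
    }
    return(newSinusoidFit(series, cf0, se, tv, pv,
                          as.numeric(X0 %*% cf0[names(cf0) != "a4"]),
                          res0, as.integer(obs), as.integer(nobs - k),
                          TRUE, withTrend, FALSE, intH,
                          "exact fit at starting values"))
  }
  lower <- c(rep(-Inf, 3), periodBandH[1] / intH, if (withTrend) -Inf)
  upper <- c(rep(Inf, 3), periodBandH[2] / intH, if (withTrend) Inf)
  form <- if (withTrend)
    y ~ a1 * cos(2 * pi * tt / a4) + a2 * sin(2 * pi * tt / a4) + a3 +
      a5 * tt
  else
    y ~ a1 * cos(2 * pi * tt / a4) + a2 * sin(2 * pi * tt / a4) + a3

  dat <- data.frame(y = y, tt = tt)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    ## flagged non-convergent result carrying the starting-value fit
    X <- harmonicDesign(tt, start$a4, withTrend)
    cfLin <- unlist(start)[c("a1", "a2", "a3", if (withTrend) "a5")]
    fitted0 <- as.numeric(X %*% cfLin)
    cf <- unlist(start)
    se <- tv <- pv <- setNames(rep(NA_real_, k), names(cf))
    return(newSinusoidFit(series, cf, se, tv, pv, fitted0, y - fitted0,
                          as.integer(obs), as.integer(nobs - k), FALSE,
                          withTrend, FALSE, intH, conditionMessage(fit)))
  }

  cf <- coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  se <- tv <- pv <- setNames(rep(NA_real_, length(cf)), names(cf))
  if (!is.null(sm)) {
    se[rownames(sm)] <- sm[, "Std. Error"]
    tv[rownames(sm)] <- sm[, "t value"]
    pv[rownames(sm)] <- sm[, "Pr(>|t|)"]
  }
  conv <- isTRUE(fit$convInfo$isConv)
  if (min(cf["a4"] - lower[4], upper[4] - cf["a4"]) < 1e-6)
    warning("fitted period pinned at the search-band edge (",
            round(cf["a4"] * intH, 2), " h)")
  newSinusoidFit(series, cf, se, tv, pv, as.numeric(fitted(fit)),
                 as.numeric(residuals(fit)), as.integer(obs),
                 as.integer(nobs - length(cf)), conv, withTrend, FALSE,
                 intH, fit$convInfo$stopMessage %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

newSinusoidFit <- function(series, cf, se, tv, pv, fitted, resid, tIndex,
                           df, converged, withTrend, periodFixed, intH,
                           msg) {
  phi <- atan2(cf["a2"], cf["a1"])
  tStar <- (phi %% (2 * pi)) / (2 * pi) * cf["a4"]   # steps past t = 0
  h1 <- clockHours(seriesTimes(series)[1])
  ## index t maps to the slot midpoint (counts accrue over the window)
  acro <- (h1 + (tStar - 1) * intH + intH / 2) %% 24
  new("SinusoidFit", taxon = taxonName(series), coefficients = cf,
      se = se, tvalues = tv, pvalues = pv,
      periodHours = unname(cf["a4"]) * intH,
      amplitude = unname(sqrt(cf["a1"]^2 + cf["a2"]^2)),
      acrophaseHours = unname(acro), fitted = fitted, residuals = resid,
      tIndex = tIndex, df = as.integer(df), converged = converged,
      withTrend = withTrend, periodFixed = periodFixed,
      intervalHours = intH, message = as.character(msg))
}

#' Wald significance of the fitted period
#'
#' Two-sided p-value from `t = a4 / se(a4)` on the fit's residual degrees
#' of freedom. The plain least-squares standard error is used; residual
#' autocorrelation is not corrected for (see the vignette for the
#' caveat).
#'
#' @param fit A converged [SinusoidFit-class] with a free period.
#' @return The p-value, or `NA` (with a warning) when the covariance was
#'   singular.
#' @export
periodSignificance <- function(fit) {
  if (fit@periodFixed) stop("period was fixed, not estimated")
  se <- fit@se["a4"]
  if (is.na(se)) {
    warning("period standard error unavailable (singular covariance)")
    return(NA_real_)
  }
  if (se == 0) return(0)                    # zero-error limit
  unname(2 * pt(-abs(fit@coefficients["a4"] / se), df = fit@df))
}

#' Residual diagnostics for a sinusoid fit
#'
#' Plot-ready residual-versus-fitted pairs and a residual histogram with
#' a configurable number of equal-width bins; histogram counts always sum
#' to the number of residuals.
#'
#' @param fit A [SinusoidFit-class].
#' @param bins Number of histogram bins (default 10).
#' @return A list: `pairs` (data frame `fitted`, `residual`), `breaks`,
#'   `counts`.
#' @export
residualDiagnostics <- function(fit, bins = 10) {
  r <- fit@residuals
  rng <- range(r)
  if (diff(rng) <= 1e-12 * max(1, max(abs(r)))) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    counts <- length(r)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    counts <- as.integer(table(cut(r, breaks, include.lowest = TRUE)))
  }
  list(pairs = data.frame(fitted = fit@fitted, residual = r),
       breaks = breaks, counts = counts)
}

#' Export sinusoid fits as a flat summary table
#'
#' One row per fit: coefficients, standard errors, per-coefficient
#' p-values, the period in hours and its p-value -- the layout of a
#' periodic-activity summary table.
#'
#' @param fits A named list of [SinusoidFit-class] objects (names become
#'   the `series` column).
#' @param file Optional TSV path.
#' @return The summary data frame (invisibly if `file` is given).
#' @export
exportFitTable <- function(fits, file = NULL) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cf <- f@coefficients
    data.frame(
      series = nm, taxon = f@taxon,
      a1 = unname(cf["a1"]), a2 = unname(cf["a2"]), a3 = unname(cf["a3"]),
      a5 = if ("a5" %in% names(cf)) unname(cf["a5"]) else NA_real_,
      period_h = f@periodHours,
      period_se_h = unname(f@se["a4"]) * f@intervalHours,
      period_p = if (f@periodFixed) NA_real_ else periodSignificance(f),
      amplitude = f@amplitude, acrophase_h = f@acrophaseHours,
      n = length(f@residuals), converged = f@converged)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
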