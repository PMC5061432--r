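## Central S4 containers. Timestamps are POSIXct in local PST (UTC-8) and
## label the start of a sampling window.

#' @import methods
#' @importFrom stats approx coef complete.cases cor fitted lm median
#'   na.omit pnorm pt qnorm residuals rnorm rpois runif sd setNames var
#' @importFrom utils read.delim write.table head tail
NULL

setOldClass(c("POSIXct", "POSIXt"))

#' Regular time series of normalized animal counts
#'
#' Per-taxon abundance on a regular 4-hour grid, in individuals per 10
#' minutes of usable footage. Missing slots are `NA` and are dropped
#' pairwise by downstream model fits and cross-correlations.
#'
#' @slot taxon Taxon label.
#' @slot timestamps `POSIXct` slot-start times on an exact 4-hour grid.
#' @slot values Non-negative normalized abundances (`NA` = missing slot).
#'
#' @seealso [pairAndNormalize()], [fitSinusoid()], [computeWaveform()]
#' @export
setClass("CountSeries",
  representation(taxon = "character", timestamps = "POSIXct",
                 values = "numeric"))

setValidity("CountSeries", function(object) {
  msg <- character()
  if (length(object@taxon) != 1L) msg <- c(msg, "taxon must be length 1")
  if (length(object@timestamps) != length(object@values))
    msg <- c(msg, "timestamps and values differ in length")
  if (length(object@timestamps) >= 2L) {
    d <- diff(as.numeric(object@timestamps)) / 3600
    if (max(abs(d - 4)) > 1e-6)
      msg <- c(msg, "grid spacing must be exactly 4 h")
  }
  v <- object@values
  if (any(v[!is.na(v)] < 0)) msg <- c(msg, "values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Regular time series of one environmental variable
#'
#' One scalar sensor variable on a regular grid (1 h for raw binned data,
#' 4 h after averaging onto the biological grid). Circular variables (flow
#' direction) are stored in degrees `[0, 360)` and flagged so that every
#' averaging step uses the vector (unit-resultant) mean.
#'
#' @slot variable Variable label, e.g. `"flow_magnitude"`.
#' @slot units Unit string, e.g. `"m/s"`.
#' @slot timestamps `POSIXct` window-start times on a regular grid.
#' @slot values Numeric values (`NA` = missing).
#' @slot circular `TRUE` for directional (angular) variables.
#'
#' @seealso [binHourly()], [average4h()], [lombScargle()]
#' @export
setClass("EnvSeries",
  representation(variable = "character", units = "character",
                 timestamps = "POSIXct", values = "numeric",
                 circular = "logical"))

setValidity("EnvSeries", function(object) {
  msg <- character()
  if (length(object@variable) != 1L) msg <- c(msg, "variable must be length 1")
  if (length(object@timestamps) != length(object@values))
    msg <- c(msg, "timestamps and values differ in length")
  if (length(object@timestamps) >= 2L) {
    d <- diff(as.numeric(object@timestamps))
    if (max(abs(d - d[1])) > 1e-6)
      msg <- c(msg, "timestamps must be on a regular grid")
  }
  if (isTRUE(object@circular)) {
    v <- object@values[!is.na(object@values)]
    if (any(v < 0 | v >= 360))
      msg <- c(msg, "circular values must lie in [0, 360) degrees")
  }
  if (length(msg)) msg else TRUE
})

#' Free-period sinusoidal least-squares fit
#'
#' Result of fitting `a1*cos(2*pi*t/a4) + a2*sin(2*pi*t/a4) + a3 [+ a5*t]`
#' to a 4-hourly count series, with `t` the integer slot index. The fitted
#' period `a4` is estimated in 4-h steps and reported in hours; amplitude
#' and acrophase are derived from `(a1, a2)`.
#'
#' @slot taxon Taxon label of the fitted series.
#' @slot coefficients Named vector `a1, a2, a3, a4[, a5]` (`a4` in 4-h steps).
#' @slot se,tvalues,pvalues Per-coefficient Wald statistics from the
#'   Jacobian covariance at the optimum.
#' @slot periodHours Fitted period in hours (`a4` times 4).
#' @slot amplitude `sqrt(a1^2 + a2^2)`, individuals per 10 min.
#' @slot acrophaseHours Clock time (hours after local midnight) of the
#'   first fitted maximum.
#' @slot fitted,residuals Fitted values and residuals on non-missing slots.
#' @slot tIndex Integer slot indices of the non-missing observations.
#' @slot df Residual degrees of freedom.
#' @slot converged `TRUE` if the optimizer met its tolerances.
#' @slot withTrend `TRUE` if the linear trend term `a5*t` was included.
#' @slot periodFixed `TRUE` if the period was held fixed (harmonic
#'   regression) rather than estimated.
#' @slot intervalHours Sampling interval of the series (4).
#' @slot message Optimizer diagnostic message.
#' @export
setClass("SinusoidFit",
  representation(taxon = "character", coefficients = "numeric",
                 se = "numeric", tvalues = "numeric", pvalues = "numeric",
                 periodHours = "numeric", amplitude = "numeric",
                 acrophaseHours = "numeric", fitted = "numeric",
                 residuals = "numeric", tIndex = "integer", df = "integer",
                 converged = "logical", withTrend = "logical",
                 periodFixed = "logical", intervalHours = "numeric",
                 message = "character"))

setValidity("SinusoidFit", function(object) {
  msg <- character()
  if (length(object@fitted) != length(object@residuals))
    msg <- c(msg, "fitted and residuals differ in length")
  if (length(object@amplitude) == 1L && !is.na(object@amplitude) &&
      object@amplitude < 0)
    msg <- c(msg, "amplitude must be >= 0")
  if (length(object@periodHours) == 1L && !is.na(object@periodHours) &&
      object@periodHours <= 0)
    msg <- c(msg, "period must be > 0")
  if (length(msg)) msg else TRUE
})

#' Lomb-Scargle periodogram of an hourly environmental series
#'
#' Variance-normalized Lomb-Scargle power over a period band, with the
#' Horne-Baliunas effective number of independent frequencies and the
#' derived significance threshold at level `alpha`.
#'
#' @slot variable Variable label.
#' @slot periods Period grid in hours (decreasing frequency order).
#' @slot power Normalized power at each grid period.
#' @slot alpha Significance level of the threshold line.
#' @slot nEff Horne-Baliunas effective number of independent frequencies.
#' @slot thresholdPower Power above which a peak is significant at `alpha`.
#' @slot peakPeriod,peakPower,peakP Band-wide maximum and its false-alarm
#'   probability.
#' @slot n Number of non-missing samples used.
#' @export
setClass("Periodogram",
  representation(variable = "character", periods = "numeric",
                 power = "numeric", alpha = "numeric", nEff = "numeric",
                 thresholdPower = "numeric", peakPeriod = "numeric",
                 peakPower = "numeric", peakP = "numeric", n = "integer"))

setValidity("Periodogram", function(object) {
  msg <- character()
  if (length(object@periods) != length(object@power))
    msg <- c(msg, "periods and power differ in length")
  if (any(object@power < -1e-12, na.rm = TRUE))
    msg <- c(msg, "power must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Positive-lag cross-correlation between environment and biology
#'
#' Sample cross-correlation `ccf(k)` of an environmental series (leading)
#' against a biological count series, at non-negative lags that are
#' multiples of 4 h, with the analytic white-noise critical values
#' `z/sqrt(n)` at alpha 0.05 and 0.10.
#'
#' @slot taxon,envVariable Labels of the two series.
#' @slot lagsHours Non-negative lags in hours (multiples of 4).
#' @slot ccf Correlation values in `[-1, 1]`.
#' @slot n Paired sample size.
#' @slot crit05,crit10 `qnorm(0.975)/sqrt(n)` and `qnorm(0.95)/sqrt(n)`.
#' @export
setClass("CCFResult",
  representation(taxon = "character", envVariable = "character",
                 lagsHours = "numeric", ccf = "numeric", n = "integer",
                 crit05 = "numeric", crit10 = "numeric"))

setValidity("CCFResult", function(object) {
  msg <- character()
  if (length(object@lagsHours) != length(object@ccf))
    msg <- c(msg, "lags and ccf differ in length")
  if (any(object@lagsHours < 0)) msg <- c(msg, "lags must be >= 0")
  if (any(abs(object@ccf) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "|ccf| must be <= 1")
  if (length(object@crit05) == 1L && length(object@crit10) == 1L &&
      !(object@crit05 > object@crit10 && object@crit10 > 0))
    msg <- c(msg, "critical values must satisfy crit05 > crit10 > 0")
  if (length(msg)) msg else TRUE
})

#' Redundancy analysis (constrained ordination) result
#'
#' PCA of the fitted values of a multivariate linear regression of the
#' centered species matrix on z-scored environmental predictors, after
#' lagging biology behind environment. Axis signs are canonicalized so the
#' predictor with the largest absolute loading is positive on each axis.
#'
#' @slot eigenvalues Constrained eigenvalues, non-increasing.
#' @slot propExplained Fraction of total response variance per axis.
#' @slot siteScores Standardized site (observation) scores, slots x axes.
#' @slot speciesScores Species scores, eigenvectors weighted by
#'   `sqrt(eigenvalue)` (correlation-biplot convention), taxa x axes.
#' @slot envScores Predictor biplot scores: correlation of each z-scored
#'   predictor with each axis's site scores, in `[-1, 1]`.
#' @slot lagHours Lag applied to the biological matrix, hours.
#' @slot totalVariance Total variance of the centered response matrix.
#' @slot dropped Names of predictors dropped for collinearity.
#' @export
setClass("RDAResult",
  representation(eigenvalues = "numeric", propExplained = "numeric",
                 siteScores = "matrix", speciesScores = "matrix",
                 envScores = "matrix", lagHours = "numeric",
                 totalVariance = "numeric", dropped = "character"))

setValidity("RDAResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(ev < -1e-10)) msg <- c(msg, "eigenvalues must be >= 0")
  if (length(ev) >= 2L && any(diff(ev) > 1e-10))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (sum(ev) > object@totalVariance + 1e-8)
    msg <- c(msg, "constrained variance cannot exceed total variance")
  if (length(object@envScores) &&
      any(abs(object@envScores) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "env biplot scores must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Time-of-day waveform with MESOR threshold
#'
#' Clock-time bin means (+/- sample sd) across sampling days: 6 bins of
#' 4 h for biological series, 24 bins of 1 h for environmental series. The
#' MESOR (Midline Estimated Statistic Of Rhythm) is the unweighted mean of
#' the bin means; bins strictly above it form the peak.
#'
#' @slot label Series label (taxon or variable).
#' @slot binStarts Clock hours at which bins start.
#' @slot binWidth Bin width in hours.
#' @slot binMeans,binSds,binCounts Per-bin mean, sample sd and number of
#'   contributing days.
#' @slot mesor Mean of the non-missing bin means.
#' @slot peakBins Start hours of bins with mean strictly above the MESOR.
#' @slot phaseClass `"D"`, `"N"`, `"C"`, `"mixed"`, or `NA` before
#'   classification.
#' @export
setClass("WaveformResult",
  representation(label = "character", binStarts = "numeric",
                 binWidth = "numeric", binMeans = "numeric",
                 binSds = "numeric", binCounts = "integer",
                 mesor = "numeric", peakBins = "numeric",
                 phaseClass = "character"))

setValidity("WaveformResult", function(object) {
  msg <- character()
  nb <- length(object@binStarts)
  if (length(object@binMeans) != nb || length(object@binSds) != nb)
    msg <- c(msg, "bin vectors differ in length")
  if (abs(nb * object@binWidth - 24) > 1e-9)
    msg <- c(msg, "bin count times bin width must equal 24 h")
  mm <- object@binMeans[!is.na(object@binMeans)]
  if (length(mm) && length(object@mesor) == 1L && !is.na(object@mesor) &&
      abs(object@mesor - mean(mm)) > 1e-9)
    msg <- c(msg, "mesor must equal the mean of the bin means")
  if (length(msg)) msg else TRUE
})

#' Night window for phase classification
#'
#' Local clock hours of sunset (`nightStart`) and sunrise (`nightEnd`);
#' windows may wrap midnight. Defaults per campaign month approximate the
#' Barkley Canyon photoperiod: summer 21:30-05:30, winter 16:45-08:00.
#'
#' @slot nightStart,nightEnd Clock hours in `[0, 24)`.
#' @export
setClass("NightWindow",
  representation(nightStart = "numeric", nightEnd = "numeric"))

setValidity("NightWindow", function(object) {
  if (object@nightStart < 0 || object@nightStart >= 24 ||
      object@nightEnd < 0 || object@nightEnd >= 24)
    "night window hours must lie in [0, 24)" else TRUE
})

#' Synthetic study bundle
#'
#' One or more synthetic monthly campaigns: per-month transect-leg tables,
#' hourly environmental tables, and a manifest of the true generating
#' parameters (for recovery tests).
#'
#' @slot transects Named list (per month) of transect-record data frames:
#'   `timestamp`, `leg_id`, `usable_minutes`, one column per taxon.
#' @slot env Named list (per month) of hourly environmental data frames:
#'   `timestamp`, `ns_velocity`, `ew_velocity`, `temperature`, `oxygen`,
#'   `chlorophyll`, `density`.
#' @slot manifest True generating parameters, seed and generator choices.
#' @export
setClass("StudyBundle",
  representation(transects = "list", env = "list", manifest = "list"))

setValidity("StudyBundle", function(object) {
  msg <- character()
  if (length(object@transects) && is.null(names(object@transects)))
    msg <- c(msg, "transect tables must be named by month")
  if (length(object@env) && is.null(names(object@env)))
    msg <- c(msg, "env tables must be named by month")
  if (length(msg)) msg else TRUE
})
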