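## Constructors, accessors, coercions and show methods.

#' Construct a CountSeries
#'
#' @param taxon Taxon label.
#' @param timestamps `POSIXct` slot-start times on an exact 4-h grid (or
#'   anything `as.POSIXct` accepts, interpreted in local PST).
#' @param values Normalized abundances, individuals per 10 min; `NA` marks
#'   a missing slot.
#' @return A [CountSeries-class] object.
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2013-06-01", tz = localTimezone()),
#'           by = 4 * 3600, length.out = 12)
#' CountSeries("A. fimbria", ts, rpois(12, 5))
CountSeries <- function(taxon, timestamps, values) {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = localTimezone())
  new("CountSeries", taxon = as.character(taxon), timestamps = timestamps,
      values = as.numeric(values))
}

#' Construct an EnvSeries
#'
#' @param variable Variable label.
#' @param timestamps `POSIXct` window-start times on a regular grid.
#' @param values Numeric values; `NA` marks a missing window.
#' @param units Unit string.
#' @param circular `TRUE` for angular variables (degrees in `[0, 360)`).
#' @return An [EnvSeries-class] object.
#' @export
EnvSeries <- function(variable, timestamps, values, units = "",
                      circular = FALSE) {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = localTimezone())
  new("EnvSeries", variable = as.character(variable), units = units,
      timestamps = timestamps, values = as.numeric(values),
      circular = circular)
}

#' Construct a NightWindow
#'
#' @param nightStart,nightEnd Local clock hours of sunset and sunrise;
#'   the window may wrap midnight (start > end).
#' @return A [NightWindow-class] object.
#' @export
#' @examples
#' NightWindow(21.5, 5.5)  # summer night at Barkley Canyon
NightWindow <- function(nightStart, nightEnd) {
  new("NightWindow", nightStart = nightStart, nightEnd = nightEnd)
}

#' Default night window for a campaign month
#'
#' Summer (April-September) nights run 21:30-05:30 local PST, winter
#' (October-March) nights 16:45-08:00, approximating the photoperiod at
#' the study latitude; both are configurable via [NightWindow()].
#'
#' @param month Integer month 1-12, or a month name/abbreviation.
#' @return A [NightWindow-class] object.
#' @export
defaultNightWindow <- function(month) {
  if (is.character(month))
    month <- match(tolower(substr(month, 1, 3)), tolower(month.abb))
  if (is.na(month) || month < 1 || month > 12)
    stop("unrecognized month")
  if (month >= 4 && month <= 9) NightWindow(21.5, 5.5)
  else NightWindow(16.75, 8)
}

## ---- accessors -----------------------------------------------------------

#' @rdname CountSeries-class
#' @export
setMethod("seriesTimes", "CountSeries", function(x) x@timestamps)
#' @rdname EnvSeries-class
#' @export
setMethod("seriesTimes", "EnvSeries", function(x) x@timestamps)
#' @rdname CountSeries-class
#' @export
setMethod("seriesValues", "CountSeries", function(x) x@values)
#' @rdname EnvSeries-class
#' @export
setMethod("seriesValues", "EnvSeries", function(x) x@values)
#' @rdname CountSeries-class
#' @export
setMethod("taxonName", "CountSeries", function(x) x@taxon)
#' @rdname SinusoidFit-class
#' @export
setMethod("taxonName", "SinusoidFit", function(x) x@taxon)
#' @rdname EnvSeries-class
#' @export
setMethod("varName", "EnvSeries", function(x) x@variable)
#' @rdname Periodogram-class
#' @export
setMethod("varName", "Periodogram", function(x) x@variable)
#' @rdname CountSeries-class
#' @export
setMethod("nObs", "CountSeries", function(x) sum(!is.na(x@values)))
#' @rdname EnvSeries-class
#' @export
setMethod("nObs", "EnvSeries", function(x) sum(!is.na(x@values)))

#' @rdname SinusoidFit-class
#' @export
setMethod("fittedPeriod", "SinusoidFit", function(x) x@periodHours)

#' @rdname SinusoidFit-class
#' @export
setMethod("coefTable", "SinusoidFit", function(x) {
  data.frame(coefficient = names(x@coefficients),
             estimate = unname(x@coefficients),
             se = unname(x@se[names(x@coefficients)]),
             t = unname(x@tvalues[names(x@coefficients)]),
             p = unname(x@pvalues[names(x@coefficients)]),
             row.names = NULL)
})

#' @rdname SinusoidFit-class
#' @export
setMethod("isConverged", "SinusoidFit", function(x) x@converged)
#' @rdname SinusoidFit-class
#' @export
setMethod("rhythmAmplitude", "SinusoidFit", function(x) x@amplitude)
#' @rdname SinusoidFit-class
#' @export
setMethod("acrophase", "SinusoidFit", function(x) x@acrophaseHours)
#' @rdname SinusoidFit-class
#' @export
setMethod("residuals", "SinusoidFit", function(object, ...) object@residuals)
#' @rdname SinusoidFit-class
#' @export
setMethod("fitted", "SinusoidFit", function(object, ...) object@fitted)

#' @rdname Periodogram-class
#' @export
setMethod("peakPeriod", "Periodogram", function(x) x@peakPeriod)
#' @rdname Periodogram-class
#' @export
setMethod("peakPvalue", "Periodogram", function(x) x@peakP)
#' @rdname Periodogram-class
#' @export
setMethod("powerThreshold", "Periodogram", function(x) x@thresholdPower)

#' @rdname CCFResult-class
#' @export
setMethod("ccfLags", "CCFResult", function(x) x@lagsHours)
#' @rdname CCFResult-class
#' @export
setMethod("ccfValues", "CCFResult", function(x) x@ccf)
#' @rdname CCFResult-class
#' @export
setMethod("criticalValues", "CCFResult",
          function(x) c(crit05 = x@crit05, crit10 = x@crit10))

#' @rdname RDAResult-class
#' @export
setMethod("rdaEigenvalues", "RDAResult", function(x) x@eigenvalues)
#' @rdname RDAResult-class
#' @export
setMethod("propExplained", "RDAResult", function(x) x@propExplained)
#' @rdname RDAResult-class
#' @export
setMethod("speciesScores", "RDAResult", function(x) x@speciesScores)
#' @rdname RDAResult-class
#' @export
setMethod("siteScores", "RDAResult", function(x) x@siteScores)
#' @rdname RDAResult-class
#' @export
setMethod("biplotScores", "RDAResult", function(x) x@envScores)

#' @rdname WaveformResult-class
#' @export
setMethod("mesor", "WaveformResult", function(x) x@mesor)
#' @rdname WaveformResult-class
#' @export
setMethod("peakBins", "WaveformResult", function(x) x@peakBins)
#' @rdname WaveformResult-class
#' @export
setMethod("phaseClass", "WaveformResult", function(x) x@phaseClass)

## ---- coercions -----------------------------------------------------------

#' @export
setMethod("as.data.frame", "CountSeries",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(timestamp = x@timestamps, value = x@values, taxon = x@taxon)
})

#' @export
setMethod("as.data.frame", "EnvSeries",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(timestamp = x@timestamps, value = x@values,
             variable = x@variable)
})

#' @export
setMethod("as.data.frame", "WaveformResult",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(bin_start_h = x@binStarts, mean = x@binMeans, sd = x@binSds,
             n_days = x@binCounts,
             above_mesor = !is.na(x@binMeans) & x@binMeans > x@mesor)
})

#' @export
setMethod("as.data.frame", "CCFResult",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(lag_h = x@lagsHours, ccf = x@ccf, crit05 = x@crit05,
             crit10 = x@crit10)
})

#' @export
setMethod("as.data.frame", "Periodogram",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(period_h = x@periods, power = x@power)
})

## ---- show methods --------------------------------------------------------

setMethod("show", "CountSeries", function(object) {
  cat("CountSeries:", object@taxon, "\n")
  cat(" ", length(object@values), "slots at 4 h,", nObs(object),
      "non-missing\n")
  if (length(object@timestamps))
    cat("  span:", format(object@timestamps[1]), "to",
        format(object@timestamps[length(object@timestamps)]), "\n")
})

setMethod("show", "EnvSeries", function(object) {
  sp <- if (length(object@timestamps) >= 2)
    diff(as.numeric(object@timestamps[1:2])) / 3600 else NA
  cat("EnvSeries:", object@variable,
      if (nzchar(object@units)) paste0("[", object@units, "]") else "",
      if (object@circular) "(circular)" else "", "\n")
  cat(" ", length(object@values), "samples at", sp, "h,", nObs(object),
      "non-missing\n")
})

setMethod("show", "SinusoidFit", function(object) {
  cat("SinusoidFit:", object@taxon,
      if (object@withTrend) "(with linear trend)" else "", "\n")
  cat("  period:", format(object@periodHours, digits = 5), "h",
      if (object@periodFixed) "(fixed)" else
        paste0("(p = ", format.pval(object@pvalues["a4"], digits = 3), ")"),
      "\n")
  cat("  amplitude:", format(object@amplitude, digits = 4),
      "ind/10min, acrophase:", format(object@acrophaseHours, digits = 4),
      "h\n")
  cat("  converged:", object@converged, "\n")
})

setMethod("show", "Periodogram", function(object) {
  cat("Lomb-Scargle periodogram:", object@variable, "\n")
  cat("  peak:", format(object@peakPeriod, digits = 5), "h, power",
      format(object@peakPower, digits = 4), ", p =",
      format.pval(object@peakP, digits = 3), "\n")
  cat("  threshold (alpha =", object@alpha, "):",
      format(object@thresholdPower, digits = 4), "; n_eff =",
      format(object@nEff, digits = 4), "\n")
})

setMethod("show", "CCFResult", function(object) {
  i <- which.max(object@ccf)
  cat("CCF:", object@envVariable, "->", object@taxon, "\n")
  cat("  n =", object@n, "; max ccf", format(object@ccf[i], digits = 3),
      "at lag", object@lagsHours[i], "h\n")
  cat("  critical values: +/-", format(object@crit05, digits = 3),
      "(alpha 0.05), +/-", format(object@crit10, digits = 3),
      "(alpha 0.10)\n")
})

setMethod("show", "RDAResult", function(object) {
  cat("RDA (biology lagged", object@lagHours, "h)\n")
  cat("  constrained eigenvalues:",
      paste(format(object@eigenvalues, digits = 4), collapse = ", "), "\n")
  cat("  proportion explained:",
      paste(format(object@propExplained, digits = 3), collapse = ", "),
      "\n")
  if (length(object@dropped))
    cat("  dropped (collinear):", paste(object@dropped, collapse = ", "),
        "\n")
})

setMethod("show", "WaveformResult", function(object) {
  cat("Waveform:", object@label, "(", length(object@binStarts), "bins of",
      object@binWidth, "h )\n")
  cat("  MESOR:", format(object@mesor, digits = 4), "; peak bins:",
      if (length(object@peakBins))
        paste(sprintf("%02d:00", as.integer(object@peakBins)),
              collapse = ", ") else "none", "\n")
  if (!is.na(object@phaseClass))
    cat("  phase:", object@phaseClass, "\n")
})

setMethod("show", "NightWindow", function(object) {
  cat(sprintf("NightWindow: %05.2f h to %05.2f h (local)\n",
              object@nightStart, object@nightEnd))
})

setMethod("show", "StudyBundle", function(object) {
  cat("StudyBundle:", length(object@transects), "month(s):",
      paste(names(object@transects), collapse = ", "), "\n")
  cat("  seed:", object@manifest$seed, "\n")
})
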