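## Preprocessing: from raw transect records and sensor streams to the
## regular 4-h biological and 1-h/4-h environmental series the statistics
## consume.
##
## Conventions fixed here: 4-h slots are anchored at local midnight (a
## record belongs to the slot containing its timestamp), the zero-count
## filter discards strictly above 1/3 zeros, missing slots stay missing
## (models and correlations drop them pairwise), and flow direction is the
## oceanographic heading the flow moves TOWARD, degrees clockwise from
## North.

#' Pair transect legs and normalize counts to individuals per 10 min
#'
#' Counts of both legs in a 4-h slot are summed and scaled by total
#' usable footage: `value = sum(counts) * 10 / sum(usable_minutes)`.
#' Slots with a single leg are normalized by that leg's footage (with a
#' warning) or dropped, depending on `singleLeg`. Slots with zero usable
#' minutes become missing. The output grid covers every 4-h slot between
#' the first and last record; untouched slots are `NA`.
#'
#' @param records Data frame of transect records: `timestamp` (POSIXct or
#'   ISO-8601 text), `leg_id`, `usable_minutes`, plus one count column per
#'   taxon. `usable_minutes` may be `NA` if `nominalPairMinutes` is given.
#' @param taxon Name of the count column to extract.
#' @param slotAnchor Clock hour anchoring the slot grid (default 0 =
#'   midnight, giving the canonical 6 bins/day).
#' @param nominalPairMinutes Fallback total footage per pair when
#'   durations are absent (default 20 = 2 x 10 min legs).
#' @param singleLeg `"normalize"` (default) or `"drop"`.
#' @return A [CountSeries-class].
#' @export
#' @examples
#' rec <- genCountSeries(rhythmSpec(24, 4, 5, 11), samplingSpec(rngSeed = 1))
#' pairAndNormalize(rec, "taxon1")
pairAndNormalize <- function(records, taxon, slotAnchor = 0,
                             nominalPairMinutes = 20,
                             singleLeg = c("normalize", "drop")) {
  singleLeg <- match.arg(singleLeg)
  if (!taxon %in% names(records)) stop("no count column for taxon ", taxon)
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = localTimezone())
  counts <- records[[taxon]]
  if (any(counts[!is.na(counts)] < 0) ||
      any(abs(counts[!is.na(counts)] -
              round(counts[!is.na(counts)])) > 1e-9))
    stop("counts must be non-negative integers")
  mins <- records$usable_minutes
  if (is.null(mins)) mins <- rep(NA_real_, nrow(records))
  if (any(mins[!is.na(mins)] < 0)) stop("usable_minutes must be >= 0")

  slot <- floorToSlot(ts, 4, slotAnchor)
  grid <- seq(min(slot), max(slot), by = 4 * 3600)
  vals <- rep(NA_real_, length(grid))
  key <- as.numeric(slot)
  singles <- 0L
  for (i in seq_along(grid)) {
    sel <- which(key == as.numeric(grid[i]))
    if (!length(sel)) next
    if (length(sel) == 1L) {
      if (singleLeg == "drop") next
      singles <- singles + 1L
    }
    ## absent per-leg durations fall back to the nominal leg share
    dur <- ifelse(is.na(mins[sel]), nominalPairMinutes / 2, mins[sel])
    totMin <- sum(dur)
    if (totMin <= 0) next                    # zero footage -> missing
    vals[i] <- sum(counts[sel], na.rm = TRUE) * 10 / totMin
  }
  if (singles > 0)
    warning(singles, " slot(s) had a single transect leg; normalized by ",
            "that leg's footage")
  CountSeries(taxon, grid, vals)
}

#' Zero-inflation filter
#'
#' A series is discarded when strictly more than one third of its
#' non-missing observations are zero counts: short zero-inflated series
#' make periodicity estimates unstable. Exactly 1/3 zeros is kept.
#'
#' @param series A [CountSeries-class].
#' @return `TRUE` to keep, `FALSE` to discard; the zero fraction is
#'   attached as attribute `"zeroFraction"`.
#' @export
#' @examples
#' ts <- seq(as.POSIXct("2013-06-01", tz = localTimezone()),
#'           by = 4 * 3600, length.out = 30)
#' zeroInflationFilter(CountSeries("x", ts, c(rep(0, 10), rep(2, 20))))
zeroInflationFilter <- function(series) {
  v <- seriesValues(series)
  v <- v[!is.na(v)]
  if (!length(v)) stop("series has no non-missing observations")
  frac <- sum(v == 0) / length(v)
  keep <- !(frac > 1 / 3)
  attr(keep, "zeroFraction") <- frac
  keep
}

#' Average a raw sensor stream into hourly bins
#'
#' Arithmetic mean per clock hour; hours with no samples are missing.
#' Circular variables (flow direction) are averaged as unit vectors, so
#' 350 and 10 degrees average to 0, not 180; an (anti)symmetric hour whose
#' resultant vanishes is undefined and becomes `NA` with a warning.
#'
#' @param timestamps Sample times (POSIXct or ISO-8601 text, local PST).
#' @param values Sample values.
#' @param variable,units Labels for the output series.
#' @param circular `TRUE` for angular data in degrees.
#' @return An [EnvSeries-class] on the full hourly grid spanned by the
#'   samples.
#' @export
binHourly <- function(timestamps, values, variable = "variable",
                      units = "", circular = FALSE) {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = localTimezone())
  hour <- floorToSlot(timestamps, 1)
  grid <- seq(min(hour), max(hour), by = 3600)
  key <- as.numeric(hour)
  vals <- rep(NA_real_, length(grid))
  undef <- 0L
  for (i in seq_along(grid)) {
    sel <- which(key == as.numeric(grid[i]) & !is.na(values))
    if (!length(sel)) next
    if (circular) {
      m <- circularMeanDeg(values[sel])
      if (isTRUE(attr(m, "undefined"))) undef <- undef + 1L
      vals[i] <- as.numeric(m)
    } else {
      vals[i] <- mean(values[sel])
    }
  }
  if (undef > 0)
    warning(undef, " hour(s) had a vanishing resultant; circular mean ",
            "undefined, set to NA")
  EnvSeries(variable, grid, vals, units = units, circular = circular)
}

#' Average an hourly series onto the 4-h biological grid
#'
#' Each biological slot takes the mean of the hourly values whose window
#' starts in `[slot, slot + 4h)`; at least one non-missing hour is
#' required, otherwise the slot is missing. Circular series use the
#' vector mean.
#'
#' @param series An hourly [EnvSeries-class].
#' @param slotAnchor Clock hour anchoring the 4-h grid (default 0).
#' @return An [EnvSeries-class] on the 4-h grid.
#' @export
average4h <- function(series, slotAnchor = 0) {
  ts <- seriesTimes(series); v <- seriesValues(series)
  slot <- floorToSlot(ts, 4, slotAnchor)
  grid <- seq(min(slot), max(slot), by = 4 * 3600)
  key <- as.numeric(slot)
  vals <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    sel <- which(key == as.numeric(grid[i]) & !is.na(v))
    if (!length(sel)) next
    vals[i] <- if (series@circular) as.numeric(circularMeanDeg(v[sel]))
               else mean(v[sel])
  }
  EnvSeries(varName(series), grid, vals, units = series@units,
            circular = series@circular)
}

#' Transform flow vector components to magnitude and direction
#'
#' `magnitude = sqrt(ns^2 + ew^2)` (m/s); `direction = atan2(ew, ns)`
#' mapped to `[0, 360)` degrees clockwise from North -- the heading the
#' flow moves toward (ADCP convention). A zero vector has magnitude 0 and
#' missing direction.
#'
#' @param ns,ew [EnvSeries-class] N-S and E-W velocity components on the
#'   same grid.
#' @return A list with elements `magnitude` and `direction`
#'   ([EnvSeries-class]; direction is circular).
#' @export
#' @examples
#' tt <- seq(as.POSIXct("2013-06-01", tz = localTimezone()),
#'           by = 3600, length.out = 3)
#' ns <- EnvSeries("ns_velocity", tt, c(0, -0.1, 0.1), "m/s")
#' ew <- EnvSeries("ew_velocity", tt, c(0.1, 0, 0.1), "m/s")
#' flowVectorToPolar(ns, ew)$direction
flowVectorToPolar <- function(ns, ew) {
  if (length(seriesTimes(ns)) != length(seriesTimes(ew)) ||
      any(abs(as.numeric(seriesTimes(ns)) -
              as.numeric(seriesTimes(ew))) > 1e-6))
    stop("component series must share one grid")
  n <- seriesValues(ns); e <- seriesValues(ew)
  mag <- sqrt(n^2 + e^2)
  dir <- deg360(atan2(e, n) * 180 / pi)
  dir[!is.na(mag) & mag == 0] <- NA_real_
  list(magnitude = EnvSeries("flow_magnitude", seriesTimes(ns), mag,
                             units = "m/s"),
       direction = EnvSeries("flow_direction", seriesTimes(ns), dir,
                             units = "deg", circular = TRUE))
}

#' Center and scale a series to z-scores
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation, computed
#' over non-missing values. Used on 4-h environmental averages before
#' cross-correlation and redundancy analysis.
#'
#' @param series An [EnvSeries-class] (non-circular).
#' @return A dimensionless [EnvSeries-class].
#' @export
zscoreSeries <- function(series) {
  if (series@circular) stop("z-scores are undefined for circular series")
  v <- seriesValues(series)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  s <- sd(v[ok])
  if (s == 0) stop("cannot z-score a constant series (zero sd)")
  EnvSeries(varName(series), seriesTimes(series), (v - mean(v[ok])) / s,
            units = "z-score")
}
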