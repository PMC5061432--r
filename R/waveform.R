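## Time-of-day waveform analysis: per-clock-bin means across sampling
## days, the MESOR midline (mean of bin means), peak bins strictly above
## it, and day/night phase classification.

waveformFromValues <- function(timestamps, values, binWidth, label) {
  h <- clockHours(timestamps)
  binStarts <- seq(0, 24 - binWidth, by = binWidth)
  bin <- binStarts[findInterval(h, c(binStarts, 24))]
  means <- sds <- rep(NA_real_, length(binStarts))
  counts <- integer(length(binStarts))
  for (i in seq_along(binStarts)) {
    vv <- values[bin == binStarts[i] & !is.na(values)]
    counts[i] <- length(vv)
    if (length(vv)) {
      means[i] <- mean(vv)
      sds[i] <- if (length(vv) > 1) sd(vv) else NA_real_
    }
  }
  if (any(counts == 0))
    warning(sum(counts == 0), " empty bin(s) excluded from the MESOR")
  mes <- mean(means, na.rm = TRUE)
  peaks <- binStarts[!is.na(means) & means > mes]
  new("WaveformResult", label = label, binStarts = binStarts,
      binWidth = binWidth, binMeans = means, binSds = sds,
      binCounts = counts, mesor = mes, peakBins = peaks,
      phaseClass = NA_character_)
}

#' Time-of-day waveform of a series
#'
#' Averages the series by clock bin across sampling days -- 6 bins of
#' 4 h for a biological count series, 24 bins of 1 h for an hourly
#' environmental series -- with the per-bin sample standard deviation.
#' The MESOR (mean of the bin means) is the peak threshold: bins with
#' mean strictly above it form the peak. Missing slots are excluded from
#' their bin's average; a bin with no data is missing and excluded from
#' the MESOR with a warning.
#'
#' @param x A [CountSeries-class] or [EnvSeries-class] spanning at least
#'   2 days.
#' @param ... Unused.
#' @return A [WaveformResult-class] (phase not yet classified).
#' @export
#' @examples
#' rec <- genCountSeries(rhythmSpec(24, 6, 6, 11), samplingSpec(rngSeed = 4))
#' wf <- computeWaveform(pairAndNormalize(rec, "taxon1"))
#' mesor(wf); peakBins(wf)
setMethod("computeWaveform", "CountSeries", function(x, ...) {
  if (diff(range(as.numeric(seriesTimes(x)))) < 24 * 3600)
    stop("need at least 2 days of data")
  waveformFromValues(seriesTimes(x), seriesValues(x), 4, taxonName(x))
})

#' @rdname computeWaveform
#' @export
setMethod("computeWaveform", "EnvSeries", function(x, ...) {
  if (diff(range(as.numeric(seriesTimes(x)))) < 24 * 3600)
    stop("need at least 2 days of data")
  w <- gridSpacingHours(seriesTimes(x))
  if (!w %in% c(1, 4)) stop("unsupported grid spacing: ", w, " h")
  waveformFromValues(seriesTimes(x), seriesValues(x), w, varName(x))
})

#' MESOR of a set of bin means
#'
#' The Midline Estimated Statistic Of Rhythm: the unweighted mean of the
#' (non-missing) waveform bin means.
#'
#' @param binMeans Numeric vector of bin means.
#' @return The MESOR.
#' @export
#' @examples
#' computeMesor(c(0, 1, 2, 3, 2, 1))  # 1.5
computeMesor <- function(binMeans) {
  if (all(is.na(binMeans))) stop("no non-missing bin means")
  mean(binMeans, na.rm = TRUE)
}

## is clock hour h (in [0,24)) inside the night window?
inNight <- function(h, night) {
  s <- night@nightStart; e <- night@nightEnd
  if (s > e) h >= s | h < e else h >= s & h < e
}

## does clock hour tr fall strictly inside bin [bs, bs+w) (mod 24)?
transitionInside <- function(tr, bs, w) {
  d <- (tr - bs) %% 24
  d > 1e-9 && d < w - 1e-9
}

#' Classify the activity phase of a waveform
#'
#' A classified bin containing a day/night transition (sunrise or sunset
#' falls strictly inside it) makes the series crepuscular (`"C"`);
#' otherwise bins fully in daylight give diurnal (`"D"`), fully in night
#' nocturnal (`"N"`), and a day/night mixture `"mixed"`.
#'
#' By default classification uses the dominant peak -- the bin(s) tied at
#' the waveform maximum -- because for any sinusoidal rhythm the full
#' above-MESOR set spans half the cycle and would brand every rhythm
#' crepuscular; the dominant bin carries the acrophase. `on =
#' "above-mesor"` classifies on every peak bin instead.
#'
#' @param wf A [WaveformResult-class] with non-empty peak bins.
#' @param night A [NightWindow-class] (see [defaultNightWindow()]).
#' @param on `"max"` (default) or `"above-mesor"`: which bins to
#'   classify.
#' @return The input waveform with `phaseClass` set.
#' @export
#' @examples
#' rec <- genCountSeries(rhythmSpec(24, 6, 6, 11), samplingSpec(rngSeed = 4))
#' wf <- computeWaveform(pairAndNormalize(rec, "taxon1"))
#' phaseClass(classifyPhase(wf, defaultNightWindow(6)))
classifyPhase <- function(wf, night, on = c("max", "above-mesor")) {
  on <- match.arg(on)
  pk <- wf@peakBins
  if (!length(pk)) stop("no peak bins: series has no values above MESOR")
  if (on == "max") {
    mm <- wf@binMeans[match(pk, wf@binStarts)]
    pk <- pk[mm > max(mm) - 1e-12]
  }
  w <- wf@binWidth
  crep <- vapply(pk, function(bs)
    transitionInside(night@nightStart, bs, w) ||
      transitionInside(night@nightEnd, bs, w), logical(1))
  cls <- if (any(crep)) "C" else {
    dark <- vapply(pk, function(bs) inNight(bs, night), logical(1))
    if (all(!dark)) "D" else if (all(dark)) "N" else "mixed"
  }
  wf@phaseClass <- cls
  wf
}

#' Waveform robustness to per-bin maxima
#'
#' Recomputes the waveform after removing each bin's single maximum
#' observation -- peaks that survive are not driven by one outlying
#' transect. Bins reduced below one value become missing.
#'
#' @param x A [CountSeries-class] or [EnvSeries-class] spanning at least
#'   3 days.
#' @return A list with `full` and `trimmed` [WaveformResult-class]
#'   objects and `removedPerBin` (always 1 for non-empty bins).
#' @export
robustnessCheck <- function(x) {
  ts <- seriesTimes(x); v <- seriesValues(x)
  if (diff(range(as.numeric(ts))) < 2 * 24 * 3600)
    stop("need at least 3 days of data")
  full <- computeWaveform(x)
  w <- full@binWidth
  h <- clockHours(ts)
  bin <- full@binStarts[findInterval(h, c(full@binStarts, 24))]
  drop <- logical(length(v))
  removed <- integer(length(full@binStarts))
  for (i in seq_along(full@binStarts)) {
    sel <- which(bin == full@binStarts[i] & !is.na(v))
    if (length(sel)) {
      drop[sel[which.max(v[sel])]] <- TRUE
      removed[i] <- 1L
    }
  }
  vt <- v; vt[drop] <- NA
  trimmed <- suppressWarnings(
    waveformFromValues(ts, vt, w, paste0(full@label, " (trimmed)")))
  list(full = full, trimmed = trimmed, removedPerBin = removed)
}

#' Export a waveform as TSV
#'
#' Writes the bin table (`bin_start_h`, `mean`, `sd`, `n_days`,
#' `above_mesor`) plus a one-row summary (`mesor`, `phase_class`).
#'
#' @param wf A [WaveformResult-class].
#' @param file Path of the table TSV; the summary goes to
#'   `<file>.summary.tsv`.
#' @return Invisibly, the two paths.
#' @export
exportWaveform <- function(wf, file) {
  write.table(as.data.frame(wf), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sfile <- paste0(file, ".summary.tsv")
  write.table(data.frame(label = wf@label, mesor = wf@mesor,
                         phase_class = wf@phaseClass),
              sfile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(file, sfile))
}
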