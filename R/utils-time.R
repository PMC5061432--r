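## Time helpers shared across modules.
##
## All timestamps are local Pacific Standard Time, fixed UTC-8 with no
## daylight saving ("Etc/GMT+8" in the Olson database, whose sign is
## inverted relative to the usual convention). Timestamps label the START
## of a sampling window.

#' Local timezone used throughout the package
#'
#' Fixed UTC-8 (Pacific Standard Time, no daylight saving), the local time
#' in which sampling windows, acrophases and day/night windows are
#' expressed.
#'
#' @return A length-one character string usable as a `tz` argument.
#' @export
#' @examples
#' as.POSIXct("2013-06-01 00:00:00", tz = localTimezone())
localTimezone <- function() "Etc/GMT+8"

## hours since local midnight, in [0, 24)
clockHours <- function(time) {
  lt <- as.POSIXlt(time)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

## floor a timestamp to the start of its containing slot (width in hours),
## slots anchored at local midnight plus `anchor` hours
floorToSlot <- function(time, widthH, anchor = 0) {
  h <- clockHours(time)
  slotH <- h - ((h - anchor) %% widthH)
  midnight <- as.POSIXct(trunc(as.POSIXlt(time), units = "days"))
  midnight + slotH * 3600
}

## regular grid spacing in hours; error if irregular
gridSpacingHours <- function(timestamps, what = "series") {
  if (length(timestamps) < 2L) return(NA_real_)
  d <- diff(as.numeric(timestamps)) / 3600
  if (max(abs(d - d[1])) > 1e-6) {
    stop(what, " timestamps are not on a regular grid")
  }
  d[1]
}

## hours elapsed since the first timestamp
hoursSinceStart <- function(timestamps) {
  (as.numeric(timestamps) - as.numeric(timestamps[1])) / 3600
}

## mean of angles in degrees by unit-vector averaging; returns NA (with
## attribute "undefined" = TRUE) when the resultant length is ~0, e.g. for
## antipodal directions of equal weight
circularMeanDeg <- function(deg, tol = 1e-8) {
  deg <- deg[!is.na(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < tol) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  deg360(atan2(s, c) * 180 / pi)
}

## map angles to [0, 360), guarding against the floating-point wrap
## (-1e-17 %% 360 == 360)
deg360 <- function(x) {
  x <- x %% 360
  x[!is.na(x) & x >= 360 - 1e-9] <- 0
  x
}
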