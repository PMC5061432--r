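## Synthetic-data generator: seeded biological and environmental series
## with the statistical structure the downstream analyses assume --
## 5-day campaigns, 4-h transect pairs with Poisson counts around a
## rectified sinusoidal rate, hourly environmental sinusoids (diel +
## tidal), and an optional biology-lags-environment coupling.

#' Specification of a biological rhythm
#'
#' Parameterizes the generating rate sinusoid by amplitude/acrophase
#' rather than cosine/sine coefficients; the correspondence to the fitted
#' model is `a1 = A*cos(phi)`, `a2 = A*sin(phi)` (with `phi` the acrophase
#' as an angle), `a3 = mesorLevel` and `a5 = trendSlope`.
#'
#' @param periodH Rhythm period in hours (> 0); 24 for a diel rhythm.
#' @param amplitude Rate amplitude, individuals per 10 min (>= 0).
#' @param mesorLevel Rate midline, individuals per 10 min (>= 0).
#' @param acrophaseH Clock time of the rate maximum, hours after local
#'   midnight in `[0, 24)`.
#' @param trendSlope Linear trend in the rate, individuals per 10 min per
#'   4-h step (the trend-model analogue; default 0).
#' @return A validated list of class `"RhythmSpec"`.
#' @export
#' @examples
#' rhythmSpec(periodH = 24, amplitude = 6, mesorLevel = 6, acrophaseH = 11)
rhythmSpec <- function(periodH = 24, amplitude = 0, mesorLevel = 0,
                       acrophaseH = 0, trendSlope = 0) {
  stopifnot(periodH > 0, amplitude >= 0, mesorLevel >= 0,
            acrophaseH >= 0, acrophaseH < 24)
  structure(list(periodH = periodH, amplitude = amplitude,
                 mesorLevel = mesorLevel, acrophaseH = acrophaseH,
                 trendSlope = trendSlope), class = "RhythmSpec")
}

#' Specification of a periodic environmental driver
#'
#' A baseline plus a sum of sinusoidal components (e.g. diel ~24 h and
#' semidiurnal tidal ~12.42 h) plus Gaussian noise.
#'
#' @param variableName Variable label.
#' @param components List of `list(periodH, amplitude, phaseRad)` entries;
#'   each contributes `amplitude * cos(2*pi*t/periodH - phaseRad)`.
#' @param baseline Constant level, variable units.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param units Unit string carried into the generated series.
#' @return A validated list of class `"EnvDriverSpec"`.
#' @export
#' @examples
#' envDriverSpec("flow_magnitude",
#'   components = list(list(periodH = 24, amplitude = 0.04, phaseRad = 0),
#'                     list(periodH = 12.42, amplitude = 0.02, phaseRad = 1)),
#'   baseline = 0.06, noiseSd = 0.01, units = "m/s")
envDriverSpec <- function(variableName, components = list(), baseline = 0,
                          noiseSd = 0, units = "") {
  stopifnot(noiseSd >= 0)
  for (cp in components) {
    if (is.null(cp$periodH) || cp$periodH <= 0)
      stop("all component periods must be > 0")
    if (is.null(cp$phaseRad)) cp$phaseRad <- 0
  }
  components <- lapply(components, function(cp) {
    if (is.null(cp$phaseRad)) cp$phaseRad <- 0
    if (is.null(cp$amplitude)) cp$amplitude <- 0
    cp
  })
  structure(list(variableName = variableName, components = components,
                 baseline = baseline, noiseSd = noiseSd, units = units),
            class = "EnvDriverSpec")
}

#' Specification of biology-environment coupling
#'
#' Adds `gain * driver(t - lagH)` to the biological rate, so that counts
#' follow the driver with a delay (default 12 h, the delay at which the
#' field data respond).
#'
#' @param driver Name of the driving environmental variable.
#' @param lagH Delay in hours (>= 0, a multiple of the biological
#'   sampling interval).
#' @param gain Dimensionless gain applied to the lagged driver value.
#' @return A validated list of class `"CouplingSpec"`.
#' @export
couplingSpec <- function(driver, lagH = 12, gain = 1) {
  stopifnot(lagH >= 0)
  structure(list(driver = driver, lagH = lagH, gain = gain),
            class = "CouplingSpec")
}

#' Specification of the sampling design
#'
#' @param startTime Campaign start (local PST); defaults to midnight so
#'   slot starts land on the canonical 00/04/.../20 h grid.
#' @param nDays Number of sampled days (default 5).
#' @param bioIntervalH Biological sampling interval in hours (default 4).
#' @param envIntervalH Environmental sampling interval in hours (default 1).
#' @param footageMinutesPerLeg Nominal usable footage per transect leg
#'   (default 10 min).
#' @param footageJitterSd Lognormal-ish jitter sd on leg durations
#'   (0 = fixed durations).
#' @param rngSeed Integer seed; every generator call is reproducible
#'   under it.
#' @return A validated list of class `"SamplingSpec"`.
#' @export
samplingSpec <- function(startTime = "2013-06-01 00:00:00", nDays = 5,
                         bioIntervalH = 4, envIntervalH = 1,
                         footageMinutesPerLeg = 10, footageJitterSd = 0,
                         rngSeed = 1L) {
  if (!inherits(startTime, "POSIXct"))
    startTime <- as.POSIXct(startTime, tz = localTimezone())
  stopifnot(nDays >= 1, bioIntervalH > 0, envIntervalH > 0)
  if (abs(bioIntervalH / envIntervalH -
          round(bioIntervalH / envIntervalH)) > 1e-9)
    stop("bioIntervalH must be an integer multiple of envIntervalH")
  structure(list(startTime = startTime, nDays = nDays,
                 bioIntervalH = bioIntervalH, envIntervalH = envIntervalH,
                 footageMinutesPerLeg = footageMinutesPerLeg,
                 footageJitterSd = footageJitterSd,
                 rngSeed = as.integer(rngSeed)), class = "SamplingSpec")
}

## deterministic noiseless driver value at arbitrary hours-since-midnight
envDriverValue <- function(spec, tH) {
  v <- rep(spec$baseline, length(tH))
  for (cp in spec$components)
    v <- v + cp$amplitude * cos(2 * pi * tH / cp$periodH - cp$phaseRad)
  v
}

#' Generate an hourly environmental series
#'
#' `value(t) = baseline + sum_i amplitude_i * cos(2*pi*t/period_i -
#' phase_i) + N(0, noiseSd)`, evaluated at hours since local midnight of
#' the campaign start, one sample per `envIntervalH`.
#'
#' @param spec An [envDriverSpec()].
#' @param sampling A [samplingSpec()]; `rngSeed` makes the noise
#'   reproducible.
#' @return An [EnvSeries-class] on the hourly grid.
#' @export
#' @examples
#' sp <- envDriverSpec("temp", list(list(periodH = 24, amplitude = 1,
#'                                       phaseRad = 0)))
#' genEnvSeries(sp, samplingSpec())
genEnvSeries <- function(spec, sampling) {
  stopifnot(inherits(spec, "EnvDriverSpec"), inherits(sampling, "SamplingSpec"))
  nSamp <- round(24 * sampling$nDays / sampling$envIntervalH)
  times <- sampling$startTime +
    (seq_len(nSamp) - 1) * sampling$envIntervalH * 3600
  tH <- clockHours(sampling$startTime) + (seq_len(nSamp) - 1) *
    sampling$envIntervalH
  v <- envDriverValue(spec, tH)
  if (spec$noiseSd > 0) {
    set.seed(sampling$rngSeed)
    v <- v + rnorm(nSamp, 0, spec$noiseSd)
  }
  EnvSeries(spec$variableName, times, v, units = spec$units)
}

#' Generate flow N-S and E-W component series
#'
#' Magnitudes are generated from `magSpec` (clipped at 0) and projected
#' onto a heading `dirDeg` degrees clockwise from North (the direction the
#' flow moves toward): `N-S = mag*cos(dir)`, `E-W = mag*sin(dir)`. The
#' pair round-trips through [flowVectorToPolar()].
#'
#' @param magSpec An [envDriverSpec()] for flow magnitude (m/s).
#' @param dirDeg Flow heading in degrees from North; scalar or one value
#'   per sample.
#' @param sampling A [samplingSpec()].
#' @return A list with [EnvSeries-class] elements `ns` and `ew`.
#' @export
genFlowComponents <- function(magSpec, dirDeg, sampling) {
  mag <- genEnvSeries(magSpec, sampling)
  m <- pmax(0, seriesValues(mag))
  rad <- dirDeg * pi / 180
  list(ns = EnvSeries("ns_velocity", seriesTimes(mag), m * cos(rad),
                      units = "m/s"),
       ew = EnvSeries("ew_velocity", seriesTimes(mag), m * sin(rad),
                      units = "m/s"))
}

## rate of the generating process at clock-hours-since-midnight tH and
## slot index step (1-based); driver lookup by linear interpolation
countRate <- function(rhythm, coupling, driver, tH, step) {
  lam <- rhythm$mesorLevel +
    rhythm$amplitude *
      cos(2 * pi * (tH - rhythm$acrophaseH) / rhythm$periodH) +
    rhythm$trendSlope * step
  if (!is.null(coupling) && !is.null(driver)) {
    dH <- hoursSinceStart(seriesTimes(driver)) +
      clockHours(seriesTimes(driver)[1])
    lam <- lam + coupling$gain *
      approx(dH, seriesValues(driver), xout = tH - coupling$lagH,
             rule = 2)$y
  }
  pmax(0, lam)
}

#' Generate transect-pair count records for one taxon
#'
#' Every `bioIntervalH` a pair of transect legs (`out`, `back`) is
#' generated. The Poisson rate is the rectified sinusoid
#' `max(0, mesor + A*cos(2*pi*(t - acrophase)/period) + trend*step +
#' gain*driver(t - lag))` evaluated at the slot midpoint (counts accrue
#' over the footage window; the midpoint is the one-point quadrature of
#' the window). Each leg contributes `Poisson(rate * minutes/10)` counts,
#' so the pair sum normalized by total footage recovers the rate.
#'
#' @param rhythm A [rhythmSpec()].
#' @param sampling A [samplingSpec()].
#' @param coupling Optional [couplingSpec()].
#' @param driver Optional [EnvSeries-class] named by `coupling$driver`.
#' @param taxon Column name for the counts.
#' @return A data frame of transect records: `timestamp`, `leg_id`,
#'   `usable_minutes` and a count column named after the taxon.
#' @export
#' @examples
#' rec <- genCountSeries(rhythmSpec(24, 6, 6, 11), samplingSpec(rngSeed = 7))
#' head(rec)
genCountSeries <- function(rhythm, sampling, coupling = NULL, driver = NULL,
                           taxon = "taxon1") {
  stopifnot(inherits(rhythm, "RhythmSpec"), inherits(sampling, "SamplingSpec"))
  if (!is.null(coupling) && coupling$lagH %% sampling$bioIntervalH > 1e-9)
    stop("coupling lag must be a multiple of the biological interval")
  if (sampling$footageMinutesPerLeg < 0)
    stop("footage duration must be non-negative")
  nSlots <- round(24 * sampling$nDays / sampling$bioIntervalH)
  slotStart <- sampling$startTime +
    (seq_len(nSlots) - 1) * sampling$bioIntervalH * 3600
  tMid <- clockHours(sampling$startTime) +
    (seq_len(nSlots) - 1) * sampling$bioIntervalH +
    sampling$bioIntervalH / 2
  lam <- countRate(rhythm, coupling, driver, tMid, seq_len(nSlots))

  set.seed(sampling$rngSeed)
  mins <- rep(sampling$footageMinutesPerLeg, 2 * nSlots)
  if (sampling$footageJitterSd > 0)
    mins <- pmax(1, mins + rnorm(2 * nSlots, 0, sampling$footageJitterSd))
  counts <- rpois(2 * nSlots, rep(lam, each = 2) * mins / 10)

  out <- data.frame(
    timestamp = rep(slotStart, each = 2) +
      rep(c(0, 15 * 60), nSlots),            # back leg ~15 min after out
    leg_id = rep(c("out", "back"), nSlots),
    usable_minutes = mins)
  out[[taxon]] <- counts
  out
}

#' Default synthetic study configuration
#'
#' Three taxa emulating the study community -- a diurnal swimmer with an
#' ascending trend coupled to flow magnitude, a crepuscular (dawn) taxon
#' coupled to chlorophyll, and a nocturnal taxon coupled to oxygen -- over
#' one or more 5-day monthly campaigns, with hourly environmental drivers
#' carrying diel (24 h) and tidal (12.42 h) components.
#'
#' @param months Character vector of campaign start dates (first of the
#'   month, local PST).
#' @param rngSeed Integer master seed.
#' @return A config list understood by [genStudy()].
#' @export
defaultStudyConfig <- function(months = c("2013-06-01", "2013-12-01"),
                               rngSeed = 1L) {
  list(
    months = months,
    rngSeed = as.integer(rngSeed),
    nDays = 5,
    env = list(
      flow_magnitude = envDriverSpec("flow_magnitude",
        components = list(list(periodH = 24, amplitude = 0.04,
                               phaseRad = pi),      # max flow at night
                          list(periodH = 12.42, amplitude = 0.02,
                               phaseRad = 0.5)),
        baseline = 0.06, noiseSd = 0.012, units = "m/s"),
      temperature = envDriverSpec("temperature",
        components = list(list(periodH = 12.42, amplitude = 0.05,
                               phaseRad = 0)),
        baseline = 3.6, noiseSd = 0.03, units = "degC"),
      oxygen = envDriverSpec("oxygen",
        components = list(list(periodH = 24, amplitude = 0.05,
                               phaseRad = pi)),     # minimum in early night
        baseline = 0.35, noiseSd = 0.015, units = "ml/l"),
      chlorophyll = envDriverSpec("chlorophyll",
        components = list(list(periodH = 24, amplitude = 0.10,
                               phaseRad = -pi / 2)), # night maximum
        baseline = 0.30, noiseSd = 0.03, units = "ug/l"),
      density = envDriverSpec("density",
        components = list(list(periodH = 12.42, amplitude = 0.01,
                               phaseRad = 1)),
        baseline = 1027.6, noiseSd = 0.005, units = "kg/m3")),
    flowDirectionDeg = 30,
    taxa = list(
      sablefish = list(
        rhythm = rhythmSpec(periodH = 24, amplitude = 6, mesorLevel = 6,
                            acrophaseH = 11, trendSlope = 0.05),
        coupling = couplingSpec("flow_magnitude", lagH = 12, gain = 20)),
      hagfish = list(
        rhythm = rhythmSpec(periodH = 24, amplitude = 3, mesorLevel = 3.5,
                            acrophaseH = 6),
        coupling = couplingSpec("chlorophyll", lagH = 12, gain = 4)),
      crabs = list(
        ## mesorLevel compensates the negative-coupling baseline shift
        ## (gain * oxygen baseline ~ -4.2) for an effective midline ~3
        rhythm = rhythmSpec(periodH = 24, amplitude = 1.5,
                            mesorLevel = 7.2, acrophaseH = 21),
        coupling = couplingSpec("oxygen", lagH = 12, gain = -12)))
  )
}

#' Generate a full synthetic study bundle
#'
#' For each campaign month, generates the hourly environmental table
#' (flow N-S/E-W components, temperature, oxygen, chlorophyll, density)
#' and a transect-record table with one count column per taxon, plus a
#' manifest of every true generating parameter for recovery tests.
#' Deterministic under the master seed: per-month and per-taxon substream
#' seeds are derived arithmetically from it.
#'
#' @param config A config list as returned by [defaultStudyConfig()].
#' @return A [StudyBundle-class].
#' @export
#' @examples
#' bundle <- genStudy(defaultStudyConfig(months = "2013-06-01", rngSeed = 3))
#' bundle
genStudy <- function(config) {
  if (is.null(config$rngSeed)) stop("config must carry an rngSeed")
  taxa <- names(config$taxa)
  if (anyDuplicated(taxa)) stop("clashing taxon names")
  if (anyDuplicated(names(config$env))) stop("clashing variable names")
  transects <- list(); envTabs <- list()
  for (mi in seq_along(config$months)) {
    m <- config$months[mi]
    monthSeed <- (config$rngSeed + 7919L * mi) %% .Machine$integer.max
    base <- samplingSpec(startTime = paste(m, "00:00:00"),
                         nDays = config$nDays, rngSeed = monthSeed)

    ## environmental table, one seeded stream per variable
    envSeries <- list()
    for (vi in seq_along(config$env)) {
      sp <- config$env[[vi]]
      s <- base; s$rngSeed <- (monthSeed + 101L * vi) %% .Machine$integer.max
      envSeries[[sp$variableName]] <- genEnvSeries(sp, s)
    }
    sMag <- base
    sMag$rngSeed <- (monthSeed + 577L) %% .Machine$integer.max
    flow <- genFlowComponents(config$env$flow_magnitude,
                              config$flowDirectionDeg, sMag)
    envTab <- data.frame(
      timestamp = format(seriesTimes(flow$ns), "%Y-%m-%d %H:%M:%S"),
      ns_velocity = seriesValues(flow$ns),
      ew_velocity = seriesValues(flow$ew),
      temperature = seriesValues(envSeries$temperature),
      oxygen = seriesValues(envSeries$oxygen),
      chlorophyll = seriesValues(envSeries$chlorophyll),
      density = seriesValues(envSeries$density))

    ## per-taxon count records against the month's noiseless drivers
    tab <- NULL
    for (ti in seq_along(config$taxa)) {
      tx <- config$taxa[[ti]]
      s <- base
      s$rngSeed <- (monthSeed + 131L * ti + 17L) %% .Machine$integer.max
      driver <- NULL
      if (!is.null(tx$coupling)) {
        driver <- envSeries[[tx$coupling$driver]]
        if (is.null(driver))
          stop("coupling driver not among env variables: ",
               tx$coupling$driver)
      }
      rec <- genCountSeries(tx$rhythm, s, tx$coupling, driver,
                            taxon = taxa[ti])
      if (is.null(tab)) tab <- rec else tab[[taxa[ti]]] <- rec[[taxa[ti]]]
    }
    tab$timestamp <- format(tab$timestamp, "%Y-%m-%d %H:%M:%S")
    transects[[m]] <- tab
    envTabs[[m]] <- envTab
  }
  manifest <- list(
    seed = config$rngSeed, months = config$months, nDays = config$nDays,
    taxa = lapply(config$taxa, function(tx) list(
      rhythm = unclass(tx$rhythm),
      coupling = if (is.null(tx$coupling)) NULL else unclass(tx$coupling))),
    env = lapply(config$env, unclass),
    flowDirectionDeg = config$flowDirectionDeg,
    noise_model = "independent Poisson counts per leg, rate*minutes/10",
    leg_split = "two independent legs of nominal 10 min per 4-h slot",
    timezone = localTimezone())
  new("StudyBundle", transects = transects, env = envTabs,
      manifest = manifest)
}

#' Write a study bundle to disk
#'
#' Writes, per month, `transects_<month>.tsv` and `env_hourly_<month>.tsv`,
#' plus `manifest.yaml` with the true generating parameters. Output is
#' byte-identical across reruns with the same config.
#'
#' @param bundle A [StudyBundle-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeStudy <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (m in names(bundle@transects)) {
    pt <- file.path(dir, paste0("transects_", m, ".tsv"))
    pe <- file.path(dir, paste0("env_hourly_", m, ".tsv"))
    write.table(bundle@transects[[m]], pt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bundle@env[[m]], pe, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, pt, pe)
  }
  pm <- file.path(dir, "manifest.yaml")
  writeLines(yaml::as.yaml(bundle@manifest), pm)
  invisible(c(paths, pm))
}
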