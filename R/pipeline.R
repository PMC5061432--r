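## Pipeline orchestration: synthesize or ingest raw tables, preprocess,
## fit rhythm models, run periodograms, CCF/RDA coupling and waveforms,
## and write one TSV per computed table plus a run log. A thin
## command-line wrapper over these functions ships in
## inst/scripts/diel-pipeline.R (subcommands synth/validate/run/report).

envTableColumns <- c("timestamp", "ns_velocity", "ew_velocity",
                     "temperature", "oxygen", "chlorophyll", "density")

#' Read a transect-record table
#'
#' Tab- or comma-separated, with columns `timestamp` (ISO-8601),
#' `leg_id`, `usable_minutes` and one count column per taxon (the 4-h
#' visual-count table layout).
#'
#' @param path File path.
#' @param tz Timezone of the timestamps (default local PST).
#' @return A data frame with parsed timestamps.
#' @export
readTransectTable <- function(path, tz = localTimezone()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("timestamp", "leg_id", "usable_minutes")
  if (!all(need %in% names(d)))
    stop("missing column(s): ", paste(setdiff(need, names(d)),
                                      collapse = ", "))
  d$timestamp <- as.POSIXct(d$timestamp, tz = tz)
  if (any(is.na(d$timestamp))) stop("unparseable timestamps in ", path)
  d
}

#' Read an hourly environmental table
#'
#' Tab- or comma-separated with the hourly environmental layout:
#' `timestamp`, `ns_velocity`, `ew_velocity`, `temperature`, `oxygen`,
#' `chlorophyll`, `density`.
#'
#' @inheritParams readTransectTable
#' @return A data frame with parsed timestamps.
#' @export
readHourlyEnvTable <- function(path, tz = localTimezone()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(envTableColumns %in% names(d)))
    stop("missing column(s): ",
         paste(setdiff(envTableColumns, names(d)), collapse = ", "))
  d$timestamp <- as.POSIXct(d$timestamp, tz = tz)
  if (any(is.na(d$timestamp))) stop("unparseable timestamps in ", path)
  d
}

#' Validate input files against the expected layouts
#'
#' Checks column sets, timestamp parseability and monotonicity for
#' transect and hourly environmental tables. Reporting only: always
#' returns, never throws.
#'
#' @param transectPaths,envPaths Character vectors of file paths.
#' @return A data frame with columns `file`, `issue` (zero rows when all
#'   files are well-formed).
#' @export
validateInputs <- function(transectPaths = character(),
                           envPaths = character()) {
  issues <- list()
  note <- function(f, msg) issues[[length(issues) + 1]] <<-
    data.frame(file = f, issue = msg)
  checkOne <- function(p, need) {
    if (!file.exists(p)) { note(p, "file does not exist"); return() }
    sep <- if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
    d <- tryCatch(read.delim(p, sep = sep, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(d)) { note(p, "unreadable table"); return() }
    miss <- setdiff(need, names(d))
    if (length(miss))
      note(p, paste("missing column(s):", paste(miss, collapse = ", ")))
    if ("timestamp" %in% names(d)) {
      ts <- suppressWarnings(as.POSIXct(d$timestamp,
                                        tz = localTimezone()))
      if (any(is.na(ts))) note(p, "unparseable timestamp(s)")
      else if (is.unsorted(ts)) note(p, "timestamps not monotonic")
    }
  }
  for (p in transectPaths)
    checkOne(p, c("timestamp", "leg_id", "usable_minutes"))
  for (p in envPaths) checkOne(p, envTableColumns)
  if (!length(issues))
    return(data.frame(file = character(), issue = character()))
  do.call(rbind, issues)
}

#' Build environmental series from an hourly table
#'
#' Converts an hourly environmental data frame (see
#' [readHourlyEnvTable()]) into named [EnvSeries-class] objects,
#' transforming the N-S/E-W velocity components into flow magnitude and
#' (circular) flow direction on the way.
#'
#' @param d Data frame with the hourly environmental columns.
#' @param tz Timezone for text timestamps.
#' @return A named list of [EnvSeries-class] objects: `flow_magnitude`,
#'   `flow_direction`, `temperature`, `oxygen`, `chlorophyll`, `density`.
#' @export
envSeriesFromTable <- function(d, tz = localTimezone()) {
  ts <- d$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = tz)
  ns <- EnvSeries("ns_velocity", ts, d$ns_velocity, "m/s")
  ew <- EnvSeries("ew_velocity", ts, d$ew_velocity, "m/s")
  polar <- flowVectorToPolar(ns, ew)
  list(flow_magnitude = polar$magnitude,
       flow_direction = polar$direction,
       temperature = EnvSeries("temperature", ts, d$temperature, "degC"),
       oxygen = EnvSeries("oxygen", ts, d$oxygen, "ml/l"),
       chlorophyll = EnvSeries("chlorophyll", ts, d$chlorophyll, "ug/l"),
       density = EnvSeries("density", ts, d$density, "kg/m3"))
}

#' Run the full diel-rhythm pipeline
#'
#' Orchestrates, per campaign month: pairing/normalization of transect
#' counts, the zero-inflation filter, free-period sinusoid fits for the
#' retained taxa, Lomb-Scargle periodograms of the hourly environmental
#' variables, cross-correlation of each retained taxon against each
#' rhythmic variable, a 12-h-lagged RDA on the z-scored 4-h
#' environmental averages (flow direction excluded: circular), and
#' waveforms with phase classification. Each stage's table is written as
#' TSV under `outDir`; `run.log` records the seed, package version and
#' every filtering decision; stage failures are logged and the remaining
#' independent stages still run.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `mode` (`"synth"` or `"ingest"`), `outDir`, and for synth mode the
#'   [defaultStudyConfig()] entries (plus `rngSeed`), or for ingest mode
#'   `transects` and `env` (named per-month file paths). Optional:
#'   `lagHours` (12), `maxLagSteps` (6), `periodBandH` (c(16, 32)),
#'   `lsBandH` (c(2, 48)), `ofac` (8), `trendTaxa` (taxa fitted with the
#'   trend model), `nightWindows` (named list month -> c(start, end)).
#' @return Invisibly, a nested list of result objects per month.
#' @export
#' @examples
#' cfg <- defaultStudyConfig(months = "2013-06-01", rngSeed = 11)
#' cfg$mode <- "synth"; cfg$outDir <- file.path(tempdir(), "run1")
#' res <- runPipeline(cfg)
#' names(res[["2013-06-01"]])
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  mode <- config$mode %||% "synth"
  outDir <- config$outDir %||% stop("config$outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logln <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(line, logCon); message(line)
  }
  logln("BenthicRhythms ",
        as.character(utils::packageVersion("BenthicRhythms")),
        " pipeline start; mode=", mode, "; seed=",
        config$rngSeed %||% "NA")

  lagHours <- config$lagHours %||% 12
  maxLagSteps <- config$maxLagSteps %||% 6
  periodBandH <- config$periodBandH %||% c(16, 32)
  lsBandH <- config$lsBandH %||% c(2, 48)
  ofac <- config$ofac %||% 8
  trendTaxa <- config$trendTaxa %||% character()

  if (mode == "synth") {
    if (is.null(config$rngSeed)) stop("synthesis mode requires rngSeed")
    full <- defaultStudyConfig(months = config$months %||%
                                 "2013-06-01",
                               rngSeed = config$rngSeed)
    for (nm in intersect(names(config), names(full)))
      full[[nm]] <- config[[nm]]
    bundle <- genStudy(full)
    writeStudy(bundle, file.path(outDir, "synthetic_data"))
    months <- names(bundle@transects)
    getTransects <- function(m) {
      d <- bundle@transects[[m]]
      d$timestamp <- as.POSIXct(d$timestamp, tz = localTimezone())
      d
    }
    getEnv <- function(m) {
      d <- bundle@env[[m]]
      d$timestamp <- as.POSIXct(d$timestamp, tz = localTimezone())
      d
    }
    logln("synthesized ", length(months), " month(s): ",
          paste(months, collapse = ", "))
  } else {
    months <- names(config$transects)
    if (is.null(months)) stop("ingest mode needs named transect paths")
    iss <- validateInputs(unlist(config$transects), unlist(config$env))
    if (nrow(iss)) {
      for (i in seq_len(nrow(iss)))
        logln("input issue: ", iss$file[i], ": ", iss$issue[i])
      stop("input validation failed; see ", logPath)
    }
    getTransects <- function(m) readTransectTable(config$transects[[m]])
    getEnv <- function(m) readHourlyEnvTable(config$env[[m]])
  }

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      logln("STAGE FAILED [", label, "]: ", conditionMessage(e))
      NULL
    })
  }
  results <- list()
  for (m in months) {
    logln("== month ", m, " ==")
    mdir <- file.path(outDir, gsub("[^0-9A-Za-z_-]", "_", m))
    dir.create(mdir, showWarnings = FALSE)
    tr <- getTransects(m)
    taxa <- setdiff(names(tr), c("timestamp", "leg_id", "usable_minutes"))
    envTab <- getEnv(m)
    env <- envSeriesFromTable(envTab)
    res <- list()

    ## biological series + zero filter
    series <- list(); filterRows <- list()
    for (tx in taxa) {
      s <- pairAndNormalize(tr, tx)
      keep <- zeroInflationFilter(s)
      filterRows[[tx]] <- data.frame(
        taxon = tx, n = nObs(s),
        zero_fraction = attr(keep, "zeroFraction"), kept = as.logical(keep),
        reason = if (keep) "" else "zero counts in > 1/3 of observations")
      logln("taxon ", tx, ": n=", nObs(s), ", zero fraction=",
            round(attr(keep, "zeroFraction"), 3),
            if (keep) ", kept" else ", DISCARDED")
      if (keep) series[[tx]] <- s
    }
    manifest <- do.call(rbind, filterRows)
    write.table(manifest, file.path(mdir, "filter_manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$filterManifest <- manifest
    res$series <- series

    ## sinusoid fits
    res$fits <- stage("sinusoid fits", {
      fits <- lapply(names(series), function(tx)
        fitSinusoid(series[[tx]], withTrend = tx %in% trendTaxa,
                    periodBandH = periodBandH))
      names(fits) <- names(series)
      exportFitTable(fits, file.path(mdir, "fit_summary.tsv"))
      fits
    })

    ## periodograms on hourly env (linear variables only)
    res$periodograms <- stage("periodograms", {
      pgs <- list()
      for (vn in c("flow_magnitude", "temperature", "oxygen",
                   "chlorophyll", "density")) {
        pg <- lombScargle(env[[vn]], periodBandH = lsBandH, ofac = ofac)
        exportPeriodogram(pg, file.path(mdir,
                                        paste0("periodogram_", vn,
                                               ".tsv")))
        pgs[[vn]] <- pg
        logln("periodogram ", vn, ": peak ", round(peakPeriod(pg), 2),
              " h, p=", signif(peakPvalue(pg), 3),
              if (pg@peakPower > powerThreshold(pg)) " (significant)"
              else " (n.s.)")
      }
      pgs
    })

    ## 4-h env averages
    env4 <- lapply(env, average4h)

    ## CCF of each kept taxon against each rhythmic variable
    res$ccf <- stage("cross-correlations", {
      rhythmic <- names(res$periodograms)[vapply(res$periodograms,
        function(pg) pg@peakPower > powerThreshold(pg), logical(1))]
      logln("rhythmic env variables: ",
            paste(rhythmic, collapse = ", "))
      ccfs <- list()
      for (tx in names(series)) for (vn in rhythmic) {
        cr <- crossCorrelation(env4[[vn]], series[[tx]],
                               maxLagSteps = maxLagSteps)
        exportCCF(cr, file.path(mdir, paste0("ccf_", tx, "_", vn,
                                             ".tsv")))
        ccfs[[paste(tx, vn, sep = "~")]] <- cr
      }
      ccfs
    })

    ## lagged RDA on z-scored 4-h averages (flow direction is circular
    ## and excluded)
    res$rda <- stage("redundancy analysis", {
      if (length(series) < 1) stop("no taxa retained")
      lagged <- lapply(series, lagSeries, lagH = lagHours)
      nL <- min(vapply(lagged, function(s) length(seriesValues(s)),
                       numeric(1)))
      Y <- vapply(lagged, function(s) seriesValues(s)[seq_len(nL)],
                  numeric(nL))
      vars <- c("flow_magnitude", "temperature", "oxygen", "chlorophyll",
                "density")
      X <- vapply(vars, function(vn)
        seriesValues(env4[[vn]])[seq_len(nL)], numeric(nL))
      r <- rdaFit(Y, X, lagHours = lagHours)
      rdaReport(r, file.path(mdir, "rda_scores.tsv"))
      logln("RDA: eigenvalues ",
            paste(signif(rdaEigenvalues(r), 3), collapse = ", "))
      r
    })

    ## waveforms + phase
    res$waveforms <- stage("waveforms", {
      nw <- config$nightWindows[[m]]
      night <- if (is.null(nw))
        defaultNightWindow(as.integer(format(as.POSIXct(
          paste(m, "00:00:00"), tz = localTimezone()), "%m")))
      else NightWindow(nw[1], nw[2])
      wfs <- list()
      for (tx in names(series)) {
        wf <- computeWaveform(series[[tx]])
        wf <- classifyPhase(wf, night)
        exportWaveform(wf, file.path(mdir, paste0("waveform_", tx,
                                                  ".tsv")))
        logln("waveform ", tx, ": phase ", phaseClass(wf))
        wfs[[tx]] <- wf
      }
      for (vn in c("flow_magnitude", "oxygen", "chlorophyll")) {
        wf <- computeWaveform(env[[vn]])
        exportWaveform(wf, file.path(mdir, paste0("waveform_", vn,
                                                  ".tsv")))
        wfs[[vn]] <- wf
      }
      wfs
    })
    results[[m]] <- res
  }
  logln("pipeline complete")
  invisible(results)
}

#' Read a 4-hourly counts-plus-environment table
#'
#' The combined 4-h layout: `timestamp`, one normalized count column per
#' taxon (individuals per 10 min), and optionally the 4-h-averaged
#' environmental columns.
#'
#' @inheritParams readTransectTable
#' @param taxa Names of the count columns.
#' @return A list: `counts` (named [CountSeries-class] list) and `env`
#'   (named [EnvSeries-class] list of the remaining numeric columns).
#' @export
readFourHourTable <- function(path, taxa, tz = localTimezone()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(d)) stop("missing timestamp column")
  miss <- setdiff(taxa, names(d))
  if (length(miss)) stop("missing taxon column(s): ",
                         paste(miss, collapse = ", "))
  ts <- as.POSIXct(d$timestamp, tz = tz)
  if (any(is.na(ts))) stop("unparseable timestamps in ", path)
  counts <- lapply(taxa, function(tx) CountSeries(tx, ts, d[[tx]]))
  names(counts) <- taxa
  envCols <- setdiff(names(d), c("timestamp", taxa))
  envCols <- envCols[vapply(d[envCols], is.numeric, logical(1))]
  env <- lapply(envCols, function(vn) EnvSeries(vn, ts, d[[vn]]))
  names(env) <- envCols
  list(counts = counts, env = env)
}
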