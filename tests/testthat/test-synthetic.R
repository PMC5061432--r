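test_that("environmental generator reproduces cosine extrema and baselines", {
  sp <- envDriverSpec("x", list(list(periodH = 24, amplitude = 1,
                                     phaseRad = 0)))
  s <- genEnvSeries(sp, samplingSpec(rngSeed = 1))
  v <- seriesValues(s)
  expect_equal(v[1], 1.0)          # t = 0: cosine maximum
  expect_equal(v[13], -1.0)        # t = 12 h: cosine minimum
  expect_equal(length(v), 120)     # 5 days hourly

  flat <- genEnvSeries(envDriverSpec("c", baseline = 5),
                       samplingSpec(rngSeed = 1))
  expect_true(all(seriesValues(flat) == 5))
})

test_that("generator noise variance matches an independent normal sampler", {
  sp <- envDriverSpec("x", list(list(periodH = 24, amplitude = 1,
                                     phaseRad = 0)), noiseSd = 0.1)
  noisy <- genEnvSeries(sp, samplingSpec(rngSeed = 42))
  clean <- genEnvSeries(envDriverSpec("x", sp$components),
                        samplingSpec(rngSeed = 42))
  vObs <- var(seriesValues(noisy) - seriesValues(clean))
  expect_lt(abs(vObs - 0.01), 0.003)           # within 30% of 0.1^2
  set.seed(4242)                                # independent sampler
  vRef <- var(rnorm(120, 0, 0.1))
  expect_lt(abs(vObs - vRef), 0.006)
})

test_that("flow components respect axis cases and round-trip through polar", {
  mag <- envDriverSpec("flow_magnitude", baseline = 0.1)
  fc <- genFlowComponents(mag, 90, samplingSpec(rngSeed = 1))
  expect_equal(max(abs(seriesValues(fc$ns))), 0, tolerance = 1e-12)
  expect_true(all(abs(seriesValues(fc$ew) - 0.1) < 1e-12))

  fc0 <- genFlowComponents(envDriverSpec("flow_magnitude", baseline = 0.2),
                           0, samplingSpec(rngSeed = 1))
  expect_true(all(abs(seriesValues(fc0$ns) - 0.2) < 1e-12))
  expect_equal(max(abs(seriesValues(fc0$ew))), 0, tolerance = 1e-12)

  for (dir in c(17, 135, 249, 330.5)) {
    spec <- envDriverSpec("flow_magnitude",
                          list(list(periodH = 24, amplitude = 0.03,
                                    phaseRad = 0.3)),
                          baseline = 0.08, noiseSd = 0.01)
    fc <- genFlowComponents(spec, dir, samplingSpec(rngSeed = dir))
    polar <- flowVectorToPolar(fc$ns, fc$ew)
    mags <- seriesValues(polar$magnitude)
    dirs <- seriesValues(polar$direction)
    ok <- mags > 0
    expect_true(all(abs(dirs[ok] - dir) < 1e-9))
    ref <- sqrt(seriesValues(fc$ns)^2 + seriesValues(fc$ew)^2)
    expect_equal(mags, ref, tolerance = 1e-12)
  }
})

test_that("count generator honors zero rates and the Poisson mean", {
  rec0 <- genCountSeries(rhythmSpec(24, 0, 0, 0),
                         samplingSpec(rngSeed = 5))
  expect_true(all(rec0$taxon1 == 0))

  ## flat rate 6 ind/10min: grand mean of normalized slot values over
  ## 200 seeds within 3 standard errors (slot variance ~ mesor/2)
  means <- vapply(1:200, function(s) {
    rec <- genCountSeries(rhythmSpec(24, 0, 6, 0),
                          samplingSpec(rngSeed = s))
    mean(seriesValues(pairAndNormalize(rec, "taxon1")))
  }, numeric(1))
  se <- sqrt(6 / 2 / (200 * 30))
  expect_lt(abs(mean(means) - 6), 3 * se)

  expect_error(genCountSeries(rhythmSpec(24, 0, 6, 0),
                              samplingSpec(footageMinutesPerLeg = -1)),
               "non-negative")
})

test_that("counts are non-negative integers and the rate is rectified", {
  ## amplitude >> mesor forces the raw sinusoid negative half the time
  rec <- genCountSeries(rhythmSpec(24, 10, 2, 11),
                        samplingSpec(rngSeed = 9))
  expect_true(all(rec$taxon1 >= 0))
  expect_true(all(rec$taxon1 == round(rec$taxon1)))
})

test_that("waveform peak bin tracks a strong generated acrophase", {
  hits <- vapply(1:100, function(s) {
    wf <- computeWaveform(rhythmCounts(s, amplitude = 20, mesorLevel = 20))
    peak <- wf@binStarts[which.max(wf@binMeans)]
    peak <= 11 && 11 < peak + 4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("uncoupled counts are uncorrelated with the driver", {
  inside <- vapply(1:30, function(s) {
    driver <- genEnvSeries(
      envDriverSpec("driver",
                    list(list(periodH = 24, amplitude = 1, phaseRad = 0))),
      samplingSpec(rngSeed = s))
    rec <- genCountSeries(rhythmSpec(24, 0, 6, 0),
                          samplingSpec(rngSeed = s + 1000),
                          couplingSpec("driver", lagH = 12, gain = 0),
                          driver)
    cr <- crossCorrelation(average4h(driver),
                           pairAndNormalize(rec, "taxon1"))
    abs(ccfValues(cr)[ccfLags(cr) == 12]) < cr@crit05
  }, logical(1))
  expect_gte(mean(inside), 0.8)
})

test_that("study bundles have the documented shape and are deterministic", {
  cfg <- defaultStudyConfig(months = "2013-06-01", rngSeed = 21)
  b1 <- genStudy(cfg)
  tr <- b1@transects[["2013-06-01"]]
  expect_equal(nrow(tr), 30 * 2)                     # 30 slots x 2 legs
  expect_setequal(setdiff(names(tr),
                          c("timestamp", "leg_id", "usable_minutes")),
                  c("sablefish", "hagfish", "crabs"))
  slotStarts <- unique(as.POSIXct(tr$timestamp, tz = localTimezone()) -
                         ifelse(tr$leg_id == "back", 15 * 60, 0))
  expect_equal(as.numeric(diff(sort(slotStarts)), units = "hours"),
               rep(4, 29))
  expect_named(b1@env, "2013-06-01")
  expect_equal(nrow(b1@env[[1]]), 120)

  b2 <- genStudy(cfg)
  expect_identical(b1@transects, b2@transects)
  expect_identical(b1@env, b2@env)

  d1 <- file.path(tempdir(), "studyA"); d2 <- file.path(tempdir(), "studyB")
  writeStudy(b1, d1); writeStudy(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "manifest.yaml")))

  cfg2 <- cfg
  names(cfg2$taxa)[2] <- "sablefish"                 # clash
  expect_error(genStudy(cfg2), "clashing")
})
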