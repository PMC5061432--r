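## two identical days with the given six 4-h slot values
twoDaySeries <- function(dayValues, days = 2) {
  countSeries4h(rep(dayValues, days))
}

mkWaveform <- function(means, night = NULL) {
  wf <- new("WaveformResult", label = "toy",
            binStarts = seq(0, 20, by = 4), binWidth = 4,
            binMeans = means, binSds = rep(NA_real_, 6),
            binCounts = rep(2L, 6), mesor = mean(means),
            peakBins = seq(0, 20, by = 4)[means > mean(means)],
            phaseClass = NA_character_)
  wf
}

test_that("waveform bin means, sds and MESOR follow their definitions", {
  wf <- computeWaveform(twoDaySeries(c(0, 1, 2, 3, 2, 1)))
  expect_equal(wf@binMeans, c(0, 1, 2, 3, 2, 1))
  expect_equal(mesor(wf), 1.5)
  expect_equal(peakBins(wf), c(8, 12, 16))    # means 2, 3, 2
  expect_lt(abs(mesor(wf) - mean(wf@binMeans)), 1e-12)

  ## 2 days differing by 2 in every slot -> every bin sd = sqrt(2)
  v <- c(1, 4, 2, 6, 3, 2)
  s <- countSeries4h(c(v, v + 2))
  wf2 <- computeWaveform(s)
  expect_equal(wf2@binSds, rep(sqrt(2), 6))

  ## constant series: flat waveform, empty peak
  wfc <- computeWaveform(twoDaySeries(rep(3, 6)))
  expect_true(all(wfc@binMeans == 3))
  expect_equal(mesor(wfc), 3)
  expect_length(peakBins(wfc), 0)
  expect_error(classifyPhase(wfc, NightWindow(21.5, 5.5)), "no peak")
})

test_that("MESOR is the unweighted mean of bin means", {
  expect_equal(computeMesor(rep(1, 6)), 1)
  expect_equal(computeMesor(c(0, 6)), 3)
  m <- c(0.3, 1.7, 2.2, 0.9, 1.1, 0.4)
  expect_equal(computeMesor(m + 5), computeMesor(m) + 5,
               tolerance = 1e-12)
  expect_equal(computeMesor(c(1, NA, 3)), 2)
})

test_that("phase classification follows the transition/containment rules", {
  night <- NightWindow(18, 6)
  ## single dominant day bin 08-12
  d <- classifyPhase(mkWaveform(c(0, 1, 5, 1, 0, 0)), night)
  expect_equal(phaseClass(d), "D")
  ## dominant bin 04-08 contains sunrise 06:00
  c1 <- classifyPhase(mkWaveform(c(0, 5, 1, 0, 0, 1)), night)
  expect_equal(phaseClass(c1), "C")
  ## two tied night bins 20-24 and 00-04
  n1 <- classifyPhase(mkWaveform(c(5, 1, 0, 0, 1, 5)), night)
  expect_equal(phaseClass(n1), "N")
  ## tied day and night bins, no transition inside either -> mixed
  m1 <- classifyPhase(mkWaveform(c(5, 0, 5, 0, 1, 1)),
                      NightWindow(22, 4))
  expect_equal(phaseClass(m1), "mixed")
  ## literal above-MESOR rule: dawn-side peak bin makes it crepuscular
  lit <- classifyPhase(mkWaveform(c(0, 2, 5, 2, 0, 0)), night,
                       on = "above-mesor")
  expect_equal(phaseClass(lit), "C")
})

test_that("classification is invariant to uniform scaling", {
  s <- rhythmCounts(31)
  night <- defaultNightWindow(6)
  c1 <- phaseClass(classifyPhase(computeWaveform(s), night))
  s2 <- CountSeries("x", seriesTimes(s), seriesValues(s) * 7.3)
  c2 <- phaseClass(classifyPhase(computeWaveform(s2), night))
  expect_identical(c1, c2)
})

test_that("night windows wrap midnight and vary by season", {
  expect_equal(defaultNightWindow(6)@nightStart, 21.5)
  expect_equal(defaultNightWindow("December")@nightEnd, 8)
  expect_error(defaultNightWindow(13), "month")
})

test_that("noiseless generator rates reproduce their bin averages exactly", {
  rh <- rhythmSpec(24, 4, 6, 10)
  tMid <- seq(2, by = 4, length.out = 30) %% 24
  rate <- pmax(0, 6 + 4 * cos(2 * pi * (tMid - 10) / 24))
  s <- countSeries4h(rate)
  wf <- computeWaveform(s)
  for (b in seq_along(wf@binStarts)) {
    sel <- (seq(0, by = 4, length.out = 30) %% 24) == wf@binStarts[b]
    expect_equal(wf@binMeans[b], mean(rate[sel]), tolerance = 1e-12)
  }
})

test_that("the robustness check removes one maximum per bin", {
  s <- rhythmCounts(33, amplitude = 8, mesorLevel = 8)
  rc <- robustnessCheck(s)
  expect_equal(rc$removedPerBin, rep(1L, 6))
  expect_equal(rc$trimmed@binCounts, rc$full@binCounts - 1L)
  ## a strong rhythm keeps its dominant peak bin
  expect_equal(rc$full@binStarts[which.max(rc$full@binMeans)],
               rc$trimmed@binStarts[which.max(rc$trimmed@binMeans)])

  flat <- twoDaySeries(rep(4, 6), days = 3)
  rcf <- robustnessCheck(flat)
  expect_true(all(rcf$trimmed@binMeans == 4))
})

test_that("waveform export writes bins and the summary", {
  wf <- classifyPhase(computeWaveform(rhythmCounts(34)),
                      defaultNightWindow(6))
  tmp <- tempfile(fileext = ".tsv")
  exportWaveform(wf, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("bin_start_h", "mean", "sd", "above_mesor")
                  %in% names(tab)))
  smry <- read.delim(paste0(tmp, ".summary.tsv"))
  expect_equal(smry$phase_class, phaseClass(wf))
})
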