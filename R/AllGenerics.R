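## Generics for accessors and the waveform computation. Slot access from
## user code should go through these.

#' @rdname CountSeries-class
#' @param object,x A package object.
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname CountSeries-class
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname CountSeries-class
#' @export
setGeneric("taxonName", function(x) standardGeneric("taxonName"))

#' @rdname EnvSeries-class
#' @export
setGeneric("varName", function(x) standardGeneric("varName"))

#' @rdname CountSeries-class
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @rdname SinusoidFit-class
#' @export
setGeneric("fittedPeriod", function(x) standardGeneric("fittedPeriod"))

#' @rdname SinusoidFit-class
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname SinusoidFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname SinusoidFit-class
#' @export
setGeneric("rhythmAmplitude", function(x) standardGeneric("rhythmAmplitude"))

#' @rdname SinusoidFit-class
#' @export
setGeneric("acrophase", function(x) standardGeneric("acrophase"))

#' @rdname Periodogram-class
#' @export
setGeneric("peakPeriod", function(x) standardGeneric("peakPeriod"))

#' @rdname Periodogram-class
#' @export
setGeneric("peakPvalue", function(x) standardGeneric("peakPvalue"))

#' @rdname Periodogram-class
#' @export
setGeneric("powerThreshold", function(x) standardGeneric("powerThreshold"))

#' @rdname CCFResult-class
#' @export
setGeneric("ccfLags", function(x) standardGeneric("ccfLags"))

#' @rdname CCFResult-class
#' @export
setGeneric("ccfValues", function(x) standardGeneric("ccfValues"))

#' @rdname CCFResult-class
#' @export
setGeneric("criticalValues", function(x) standardGeneric("criticalValues"))

#' @rdname RDAResult-class
#' @export
setGeneric("rdaEigenvalues", function(x) standardGeneric("rdaEigenvalues"))

#' @rdname RDAResult-class
#' @export
setGeneric("propExplained", function(x) standardGeneric("propExplained"))

#' @rdname RDAResult-class
#' @export
setGeneric("speciesScores", function(x) standardGeneric("speciesScores"))

#' @rdname RDAResult-class
#' @export
setGeneric("siteScores", function(x) standardGeneric("siteScores"))

#' @rdname RDAResult-class
#' @export
setGeneric("biplotScores", function(x) standardGeneric("biplotScores"))

#' @rdname WaveformResult-class
#' @export
setGeneric("mesor", function(x) standardGeneric("mesor"))

#' @rdname WaveformResult-class
#' @export
setGeneric("peakBins", function(x) standardGeneric("peakBins"))

#' @rdname WaveformResult-class
#' @export
setGeneric("phaseClass", function(x) standardGeneric("phaseClass"))

#' @rdname computeWaveform
#' @export
setGeneric("computeWaveform", function(x, ...) standardGeneric("computeWaveform"))
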