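#' @include roex.R
NULL

setMethod("show", "TonePipSpec", function(object) {
  cat(sprintf("TonePipSpec: %g Hz @ %g dB SPL, %g ms (%g ms %s gates), phase %s, %g/s\n",
              object@frequency, object@level, object@duration,
              object@gateDuration, object@window,
              if (isTRUE(all.equal(object@phase, 0))) "0" else "pi",
              object@presentationRate))
})

setMethod("show", "NoiseCondition", function(object) {
  if (object@isQuiet) {
    cat("NoiseCondition: quiet (no masker)\n")
  } else {
    cat(sprintf("NoiseCondition: %.1f dB overall (%.1f dB Hz-1), band %g-%g Hz\n",
                object@overallLevel, object@spectrumLevel,
                object@lowCut, object@highCut))
  }
})

setMethod("show", "SpeciesProfile", function(object) {
  cat(sprintf("SpeciesProfile '%s' on %d frequencies (%g-%g Hz)\n",
              object@name, length(object@frequencies),
              min(object@frequencies), max(object@frequencies)))
  cat("  quiet thresholds (dB SPL):",
      paste(object@quietThreshold, collapse = ", "), "\n")
  cat("  critical ratios (dB):    ",
      paste(object@criticalRatio, collapse = ", "), "\n")
  cat(sprintf("  Amax %g uV, subject SD %g dB\n", object@amplitudeMax,
              object@subjectSd))
})

setMethod("show", "AbrTrace", function(object) {
  cat(sprintf("AbrTrace: %s (%s), %s @ %g dB SPL, %s\n",
              object@subjectId, object@species,
              if (object@frequency > 0)
                sprintf("%g Hz", object@frequency) else "click",
              object@level,
              if (object@noise@isQuiet) "quiet" else
                sprintf("%.0f dB Hz-1 noise", object@noise@spectrumLevel)))
  cat(sprintf("  %d samples @ %g Hz, window %g-%g ms, replicate %s, %d epochs\n",
              length(object@samples), object@sampleRate,
              object@windowStart, object@windowEnd,
              ifelse(is.na(object@replicate), "avg", object@replicate),
              object@nEpochs))
})

setMethod("show", "AbrPeaks", function(object) {
  if (!object@found) {
    cat("AbrPeaks: no qualifying P1/N1 pair found\n")
  } else {
    cat(sprintf("AbrPeaks: P1 %.2f uV @ %.2f ms, N1 %.2f uV @ %.2f ms\n",
                object@p1Voltage, object@latencyP1, object@n1Voltage,
                object@latencyN1))
    cat(sprintf("  amplitude %.2f uV (latencies re sound-at-ear onset)\n",
                object@amplitude))
  }
})

setMethod("show", "ThresholdEstimate", function(object) {
  if (object@censored == "none") {
    cat(sprintf("ThresholdEstimate: %.1f dB SPL (midpoint of %g and %g)\n",
                object@threshold, object@lowestDetectedLevel,
                object@nextQuietestLevel))
  } else {
    cat(sprintf("ThresholdEstimate: censored (%s)\n", object@censored))
  }
})

setMethod("show", "CriticalRatio", function(object) {
  cat(sprintf("CriticalRatio: %.1f dB (threshold %.1f dB SPL - N0 %.1f dB Hz-1)\n",
              object@value, object@thresholdUsed,
              object@spectrumLevelUsed))
})

setMethod("show", "RoexFilter", function(object) {
  cat(sprintf("RoexFilter: f0 %g Hz, p %.2f, ERB %.1f Hz, K %.1f dB\n",
              object@centerFrequency, object@p, object@erb, object@kDb))
})

setMethod("show", "AbrExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("AbrExperiment: %d traces x %d samples\n", ncol(object),
              nrow(object)))
  cat(sprintf("  %d subjects, %d species, %d frequencies, %d noise classes\n",
              length(unique(cd$subject_id)), length(unique(cd$species)),
              length(unique(cd$frequency_hz)),
              length(unique(cd$noise_class))))
  m <- S4Vectors::metadata(object)
  cat(sprintf("  %g Hz sampling, window %g-%g ms, sound at ear %.2f ms\n",
              m$sampleRate, m$windowStart, m$windowEnd, m$onset))
})
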