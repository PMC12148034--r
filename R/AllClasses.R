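#' @import methods
#' @importFrom stats rnorm runif sd quantile IQR aggregate lm coef AIC
#'   anova as.formula integrate uniroot fft setNames na.omit
NULL

## Central value classes. All levels are dB SPL re 20 uPa unless a slot
## says otherwise; spectrum levels are dB Hz^-1; times/durations are ms;
## frequencies Hz; voltages uV.

#' Gated tone-pip stimulus descriptor
#'
#' Describes a short pure-tone stimulus with cosine-family (Blackman-Harris)
#' onset/offset gating, as used to evoke auditory brainstem responses.
#'
#' @slot frequency carrier frequency, Hz.
#' @slot level stimulus level, dB SPL re 20 uPa.
#' @slot duration total pip duration, ms (gates included).
#' @slot gateDuration rise (= fall) time, ms.
#' @slot window gate family identifier (currently `"blackman-harris"`).
#' @slot phase carrier starting phase, radians; 0 or pi (alternating
#'   polarity presentation).
#' @slot presentationRate stimuli per second.
#'
#' @examples
#' TonePipSpec(frequency = 2500, level = 60)
#' @export
setClass("TonePipSpec",
  slots = c(
    frequency = "numeric",
    level = "numeric",
    duration = "numeric",
    gateDuration = "numeric",
    window = "character",
    phase = "numeric",
    presentationRate = "numeric"
  )
)

setValidity("TonePipSpec", function(object) {
  msg <- character()
  if (length(object@frequency) != 1 || !is.finite(object@frequency) ||
      object@frequency <= 0)
    msg <- c(msg, "'frequency' must be a single positive number")
  if (length(object@level) != 1 || !is.finite(object@level))
    msg <- c(msg, "'level' must be a single finite number")
  if (object@duration < 2 * object@gateDuration)
    msg <- c(msg, "'duration' must be >= 2 * gateDuration (rise and fall must fit)")
  if (!isTRUE(all.equal(object@phase, 0)) && !isTRUE(all.equal(object@phase, pi)))
    msg <- c(msg, "'phase' must be 0 or pi")
  if (object@presentationRate <= 0)
    msg <- c(msg, "'presentationRate' must be positive")
  if (length(msg)) msg else TRUE
})

#' @param frequency,level,duration,gateDuration,window,phase,presentationRate
#'   see slots.
#' @rdname TonePipSpec-class
#' @export
TonePipSpec <- function(frequency, level, duration = 5, gateDuration = 1,
                        window = "blackman-harris", phase = 0,
                        presentationRate = 51.1) {
  new("TonePipSpec", frequency = frequency, level = level,
      duration = duration, gateDuration = gateDuration, window = window,
      phase = phase, presentationRate = presentationRate)
}

#' Masking-noise condition
#'
#' A band-limited flat-spectrum masker, or the quiet (no-masker)
#' condition. For a flat band, overall level and spectrum level are tied
#' by \eqn{L_{ov} = N_0 + 10\log_{10}(\Delta f)}; the validity check
#' enforces consistency within 0.5 dB.
#'
#' @slot overallLevel overall masker level, dB SPL (NA when quiet).
#' @slot spectrumLevel noise spectrum level N0, dB Hz^-1 (NA when quiet).
#' @slot lowCut,highCut band edges, Hz.
#' @slot isQuiet logical flag for the no-masker condition.
#'
#' @examples
#' NoiseCondition(overallLevel = 64, lowCut = 0, highCut = 6300)
#' quietCondition()
#' @export
setClass("NoiseCondition",
  slots = c(
    overallLevel = "numeric",
    spectrumLevel = "numeric",
    lowCut = "numeric",
    highCut = "numeric",
    isQuiet = "logical"
  )
)

setValidity("NoiseCondition", function(object) {
  msg <- character()
  if (object@highCut <= object@lowCut || object@lowCut < 0)
    msg <- c(msg, "band edges must satisfy highCut > lowCut >= 0")
  if (object@isQuiet) {
    if (!is.na(object@overallLevel) || !is.na(object@spectrumLevel))
      msg <- c(msg, "quiet condition must have NA overall and spectrum levels")
  } else {
    if (is.na(object@overallLevel) || is.na(object@spectrumLevel)) {
      msg <- c(msg, "non-quiet condition needs both overall and spectrum levels")
    } else {
      bw <- object@highCut - object@lowCut
      if (abs(object@overallLevel - object@spectrumLevel - 10 * log10(bw)) > 0.5)
        msg <- c(msg, "overallLevel - spectrumLevel must equal 10*log10(bandwidth) within 0.5 dB")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param overallLevel,spectrumLevel levels in dB SPL and dB Hz^-1; give
#'   either (the other is filled in from the bandwidth) or both.
#' @param lowCut,highCut band edges, Hz.
#' @rdname NoiseCondition-class
#' @export
NoiseCondition <- function(overallLevel = NA_real_, spectrumLevel = NA_real_,
                           lowCut = 0, highCut = 6300) {
  bw <- highCut - lowCut
  if (is.na(overallLevel) && !is.na(spectrumLevel))
    overallLevel <- spectrumLevel + 10 * log10(bw)
  if (is.na(spectrumLevel) && !is.na(overallLevel))
    spectrumLevel <- overallLevel - 10 * log10(bw)
  new("NoiseCondition", overallLevel = overallLevel,
      spectrumLevel = spectrumLevel, lowCut = lowCut, highCut = highCut,
      isQuiet = FALSE)
}

#' @rdname NoiseCondition-class
#' @export
quietCondition <- function(lowCut = 0, highCut = 6300) {
  new("NoiseCondition", overallLevel = NA_real_, spectrumLevel = NA_real_,
      lowCut = lowCut, highCut = highCut, isQuiet = TRUE)
}

#' Species-level simulation profile
#'
#' Parameters of the synthetic ABR generator for one species: audiogram
#' (quiet thresholds) and critical ratios on a shared frequency grid,
#' the saturating amplitude-growth and latency-decay laws of the evoked
#' P1/N1 complex, and the between-subject threshold spread.
#'
#' @slot name species label.
#' @slot frequencies frequency grid, Hz.
#' @slot quietThreshold quiet thresholds on the grid, dB SPL.
#' @slot criticalRatio critical ratios on the grid, dB.
#' @slot amplitudeMax asymptotic P1-N1 peak-to-peak amplitude, uV.
#' @slot amplitudeGrowth sensation-level constant of the saturating
#'   amplitude growth, dB.
#' @slot latencyMin,latencySpan P1 latency at high level and the extra
#'   latency at threshold, ms (neural part; acoustic travel is added
#'   separately).
#' @slot latencyLevelConstant sensation-level constant of latency decay, dB.
#' @slot interpeakInterval P1-to-N1 interval, ms.
#' @slot subjectSd between-subject SD of quiet thresholds, dB.
#' @export
setClass("SpeciesProfile",
  slots = c(
    name = "character",
    frequencies = "numeric",
    quietThreshold = "numeric",
    criticalRatio = "numeric",
    amplitudeMax = "numeric",
    amplitudeGrowth = "numeric",
    latencyMin = "numeric",
    latencySpan = "numeric",
    latencyLevelConstant = "numeric",
    interpeakInterval = "numeric",
    subjectSd = "numeric"
  )
)

setValidity("SpeciesProfile", function(object) {
  msg <- character()
  nf <- length(object@frequencies)
  if (length(object@quietThreshold) != nf || length(object@criticalRatio) != nf)
    msg <- c(msg, "threshold and critical-ratio maps must share the frequency grid")
  if (any(object@criticalRatio < 0))
    msg <- c(msg, "critical ratios must be >= 0")
  if (object@amplitudeMax <= 0) msg <- c(msg, "'amplitudeMax' must be > 0")
  if (object@latencyMin <= 0) msg <- c(msg, "'latencyMin' must be > 0")
  if (object@interpeakInterval <= 0)
    msg <- c(msg, "'interpeakInterval' must be > 0")
  if (object@subjectSd < 0) msg <- c(msg, "'subjectSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param name,frequencies,quietThreshold,criticalRatio,amplitudeMax,amplitudeGrowth,latencyMin,latencySpan,latencyLevelConstant,interpeakInterval,subjectSd
#'   see slots.
#' @rdname SpeciesProfile-class
#' @export
SpeciesProfile <- function(name, frequencies, quietThreshold, criticalRatio,
                           amplitudeMax = 2, amplitudeGrowth = 10,
                           latencyMin = 1.5, latencySpan = 2,
                           latencyLevelConstant = 20,
                           interpeakInterval = 1, subjectSd = 3) {
  new("SpeciesProfile", name = name, frequencies = frequencies,
      quietThreshold = quietThreshold, criticalRatio = criticalRatio,
      amplitudeMax = amplitudeMax, amplitudeGrowth = amplitudeGrowth,
      latencyMin = latencyMin, latencySpan = latencySpan,
      latencyLevelConstant = latencyLevelConstant,
      interpeakInterval = interpeakInterval, subjectSd = subjectSd)
}

#' One averaged auditory-evoked-potential trace
#'
#' An averaged evoked-potential time series (uV against ms) with its
#' full recording condition. `windowStart`/`windowEnd` are relative to
#' the playback trigger; `onset` is the time at which sound reaches the
#' ear (acoustic travel delay), the reference point for latencies.
#'
#' @slot samples voltage samples, uV.
#' @slot sampleRate Hz.
#' @slot windowStart,windowEnd recording window, ms re trigger.
#' @slot onset sound-at-ear time, ms re trigger.
#' @slot subjectId,species labels.
#' @slot frequency stimulus frequency, Hz (0 for click stimuli).
#' @slot level stimulus level, dB SPL.
#' @slot noise the [NoiseCondition-class] in effect.
#' @slot replicate replicate id (1 or 2; NA for a replicate average).
#' @slot nEpochs number of raw epochs averaged into the trace.
#' @export
setClass("AbrTrace",
  slots = c(
    samples = "numeric",
    sampleRate = "numeric",
    windowStart = "numeric",
    windowEnd = "numeric",
    onset = "numeric",
    subjectId = "character",
    species = "character",
    frequency = "numeric",
    level = "numeric",
    noise = "NoiseCondition",
    replicate = "integer",
    nEpochs = "integer"
  )
)

setValidity("AbrTrace", function(object) {
  msg <- character()
  expected <- round((object@windowEnd - object@windowStart) / 1000 *
                      object@sampleRate)
  if (length(object@samples) != expected)
    msg <- c(msg, sprintf("samples length (%d) != window x sampleRate (%d)",
                          length(object@samples), expected))
  if (object@nEpochs <= 0L) msg <- c(msg, "'nEpochs' must be > 0")
  if (!is.na(object@replicate) && !object@replicate %in% c(1L, 2L))
    msg <- c(msg, "'replicate' must be 1, 2 or NA")
  if (object@frequency < 0) msg <- c(msg, "'frequency' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Extracted P1/N1 peak description
#'
#' First positive (P1) and first negative (N1) ABR peaks of one trace.
#' Amplitude is the P1-to-N1 voltage difference; latencies are measured
#' from the sound-at-ear onset. When no qualifying peak pair exists,
#' `found` is `FALSE` and all numeric fields are NA.
#'
#' @slot p1Time,n1Time peak times, ms re trigger.
#' @slot p1Voltage,n1Voltage peak voltages, uV.
#' @slot amplitude P1 minus N1 voltage, uV.
#' @slot latencyP1,latencyN1 peak times minus sound-at-ear onset, ms.
#' @slot found logical; were both peaks present?
#' @export
setClass("AbrPeaks",
  slots = c(
    p1Time = "numeric", p1Voltage = "numeric",
    n1Time = "numeric", n1Voltage = "numeric",
    amplitude = "numeric", latencyP1 = "numeric", latencyN1 = "numeric",
    found = "logical"
  )
)

setValidity("AbrPeaks", function(object) {
  if (!object@found) return(TRUE)
  msg <- character()
  if (!(object@n1Time > object@p1Time))
    msg <- c(msg, "N1 must follow P1")
  if (!isTRUE(all.equal(object@amplitude,
                        object@p1Voltage - object@n1Voltage)))
    msg <- c(msg, "amplitude must equal p1Voltage - n1Voltage")
  if (object@latencyP1 < 0 || object@latencyN1 < 0)
    msg <- c(msg, "latencies must be >= 0 (peaks cannot precede sound at the ear)")
  if (length(msg)) msg else TRUE
})

.notFoundPeaks <- function() {
  new("AbrPeaks", p1Time = NA_real_, p1Voltage = NA_real_,
      n1Time = NA_real_, n1Voltage = NA_real_, amplitude = NA_real_,
      latencyP1 = NA_real_, latencyN1 = NA_real_, found = FALSE)
}

#' Threshold estimate with censoring status
#'
#' Result of the midpoint threshold rule: the threshold is halfway
#' between the lowest level with a detectable response and the next
#' quietest tested level. `censored` is `"above_max"` when no level
#' evoked a response and `"below_min"` when responses persisted down to
#' the lowest tested level; in both cases the threshold is NA.
#'
#' @slot threshold dB SPL (NA when censored).
#' @slot censored one of `"none"`, `"above_max"`, `"below_min"`.
#' @slot lowestDetectedLevel lowest level of the unbroken response run
#'   reaching the top tested level, dB SPL.
#' @slot nextQuietestLevel next tested level below it, dB SPL.
#' @export
setClass("ThresholdEstimate",
  slots = c(
    threshold = "numeric",
    censored = "character",
    lowestDetectedLevel = "numeric",
    nextQuietestLevel = "numeric"
  )
)

setValidity("ThresholdEstimate", function(object) {
  msg <- character()
  if (!object@censored %in% c("none", "above_max", "below_min"))
    msg <- c(msg, "unknown censoring code")
  if (object@censored == "none" &&
      !isTRUE(all.equal(object@threshold,
                        (object@lowestDetectedLevel +
                           object@nextQuietestLevel) / 2)))
    msg <- c(msg, "uncensored threshold must be the midpoint of the bracketing levels")
  if (length(msg)) msg else TRUE
})

#' Critical ratio
#'
#' Signal-to-noise ratio at masked threshold: the masked threshold
#' (dB SPL) minus the masker spectrum level (dB Hz^-1).
#'
#' @slot value critical ratio, dB.
#' @slot thresholdUsed masked threshold, dB SPL.
#' @slot spectrumLevelUsed masker spectrum level, dB Hz^-1.
#' @export
setClass("CriticalRatio",
  slots = c(value = "numeric", thresholdUsed = "numeric",
            spectrumLevelUsed = "numeric")
)

setValidity("CriticalRatio", function(object) {
  if (!isTRUE(all.equal(object@value,
                        object@thresholdUsed - object@spectrumLevelUsed)))
    "value must equal thresholdUsed - spectrumLevelUsed" else TRUE
})

#' Rounded-exponential (roex) auditory filter
#'
#' Symmetric roex(p) filter with power weighting
#' \eqn{W(g) = (1 + pg)e^{-pg}}, \eqn{g = |f - f_0|/f_0}, equivalent
#' rectangular bandwidth \eqn{ERB = 4 f_0 / p}, and efficiency
#' parameter K (the signal-to-filtered-noise ratio required at
#' threshold, dB).
#'
#' @slot centerFrequency f0, Hz.
#' @slot p dimensionless shape (slope) parameter.
#' @slot erb equivalent rectangular bandwidth, Hz.
#' @slot kDb filter efficiency K, dB.
#'
#' @examples
#' RoexFilter(2000, p = 16)           # ERB 500 Hz
#' RoexFilter(2000, erb = 500, kDb = 3)
#' @export
setClass("RoexFilter",
  slots = c(centerFrequency = "numeric", p = "numeric", erb = "numeric",
            kDb = "numeric")
)

setValidity("RoexFilter", function(object) {
  msg <- character()
  if (object@p <= 0) msg <- c(msg, "'p' must be > 0")
  if (!is.finite(object@kDb)) msg <- c(msg, "'kDb' must be finite")
  expected <- 4 * object@centerFrequency / object@p
  if (abs(object@erb - expected) > 1e-9 * expected)
    msg <- c(msg, "erb must equal 4 * centerFrequency / p")
  if (length(msg)) msg else TRUE
})

#' @param centerFrequency f0, Hz.
#' @param p shape parameter; give either `p` or `erb`.
#' @param erb equivalent rectangular bandwidth, Hz.
#' @param kDb efficiency K, dB (default 0: equal-power assumption).
#' @rdname RoexFilter-class
#' @export
RoexFilter <- function(centerFrequency, p = NULL, erb = NULL, kDb = 0) {
  if (is.null(p) && is.null(erb))
    stop("give one of 'p' or 'erb'")
  if (is.null(p)) p <- 4 * centerFrequency / erb
  if (is.null(erb)) erb <- 4 * centerFrequency / p
  new("RoexFilter", centerFrequency = centerFrequency, p = p, erb = erb,
      kDb = kDb)
}

#' Container for a set of ABR traces
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]: the
#' `"voltage"` assay holds one column per averaged trace (rows = time
#' samples), `colData` the per-trace condition metadata (`subject_id`,
#' `species`, `frequency_hz`, `level_db`, `noise_overall_db`,
#' `noise_spectrum_db`, `is_quiet`, `replicate`, `n_epochs`), and
#' `metadata()` the acquisition constants (`sampleRate`, `windowStart`,
#' `windowEnd`, `onset`, all shared across traces) plus, for simulated
#' experiments, the ground-truth manifests.
#'
#' @export
setClass("AbrExperiment", contains = "SummarizedExperiment")

setValidity("AbrExperiment", function(object) {
  msg <- character()
  need <- c("subject_id", "species", "frequency_hz", "level_db",
            "noise_overall_db", "noise_spectrum_db", "is_quiet",
            "replicate", "n_epochs")
  missing <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    msg <- c(msg, paste("colData lacks:", paste(missing, collapse = ", ")))
  if (!"voltage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'voltage' is required")
  meta <- S4Vectors::metadata(object)
  for (k in c("sampleRate", "windowStart", "windowEnd", "onset"))
    if (is.null(meta[[k]]))
      msg <- c(msg, paste0("metadata()$", k, " is required"))
  if (length(msg)) msg else TRUE
})
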