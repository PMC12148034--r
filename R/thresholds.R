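#' @include metrics.R
NULL

#' Classify response presence from a replicate pair
#'
#' A response is recorded as present only when a qualifying P1/N1 pair
#' was found in BOTH replicate measurements; one replicate alone is not
#' enough.
#'
#' @param peaks1,peaks2 [AbrPeaks-class] from the two replicates.
#' @return logical.
#' @export
classifyResponse <- function(peaks1, peaks2) {
  stopifnot(is(peaks1, "AbrPeaks"), is(peaks2, "AbrPeaks"))
  peaks1@found && peaks2@found
}

#' Estimate a threshold by the midpoint rule
#'
#' The threshold is the sound pressure level halfway between the lowest
#' level with a detectable response and the next quietest tested level
#' (with the usual 5-dB steps near threshold this is 2.5 dB below the
#' lowest detected level). Detection series are tracked down from the
#' loudest level: the anchor is the lowest level of the unbroken
#' present-run reaching the maximum tested level, so an isolated
#' detection below a miss does not move the threshold. When no level
#' evoked a response the estimate is censored `"above_max"`; when the
#' unbroken run reaches the lowest tested level it is censored
#' `"below_min"`; censored estimates carry an NA threshold.
#'
#' @param levels tested stimulus levels, dB SPL (any order, no
#'   duplicates).
#' @param present logical vector of response presence per level.
#' @return a [ThresholdEstimate-class].
#' @examples
#' lv <- c(60, 40, 30, 25, 20, 15, 10, 5)
#' estimateThreshold(lv, lv >= 15)   # threshold 12.5 dB SPL
#' @export
estimateThreshold <- function(levels, present) {
  if (length(levels) < 2) stop("need at least two tested levels")
  if (length(levels) != length(present))
    stop("'levels' and 'present' lengths differ")
  if (anyNA(levels) || anyNA(present)) stop("NA in levels or presence flags")
  if (anyDuplicated(levels)) stop("duplicate tested levels")
  o <- order(levels, decreasing = TRUE)
  lv <- levels[o]; pr <- as.logical(present[o])
  if (!pr[1])
    return(new("ThresholdEstimate", threshold = NA_real_,
               censored = "above_max",
               lowestDetectedLevel = NA_real_,
               nextQuietestLevel = NA_real_))
  runEnd <- which(!pr)[1]           # first miss walking down from the top
  if (is.na(runEnd))
    return(new("ThresholdEstimate", threshold = NA_real_,
               censored = "below_min",
               lowestDetectedLevel = lv[length(lv)],
               nextQuietestLevel = NA_real_))
  lowest <- lv[runEnd - 1L]
  nextq <- lv[runEnd]
  new("ThresholdEstimate", threshold = (lowest + nextq) / 2,
      censored = "none", lowestDetectedLevel = lowest,
      nextQuietestLevel = nextq)
}

#' @rdname ThresholdEstimate-class
#' @export
setMethod("threshold", "ThresholdEstimate", function(x) x@threshold)

#' @rdname ThresholdEstimate-class
#' @export
setMethod("censored", "ThresholdEstimate", function(x) x@censored)

#' Critical ratio from a masked threshold
#'
#' Subtracts the masker spectrum level (dB Hz^-1) from the masked
#' threshold (dB SPL). Undefined in the quiet condition (no spectrum
#' level exists) and for censored thresholds.
#'
#' @param estimate an uncensored [ThresholdEstimate-class].
#' @param noise a non-quiet [NoiseCondition-class].
#' @return a [CriticalRatio-class].
#' @examples
#' est <- estimateThreshold(c(60, 50, 45, 40), c(TRUE, TRUE, TRUE, FALSE))
#' computeCriticalRatio(est, NoiseCondition(spectrumLevel = 16))
#' @export
computeCriticalRatio <- function(estimate, noise) {
  stopifnot(is(estimate, "ThresholdEstimate"), is(noise, "NoiseCondition"))
  if (isQuiet(noise))
    stop("critical ratio undefined: the quiet condition has no spectrum level")
  if (estimate@censored != "none")
    stop("critical ratio undefined for a censored threshold (",
         estimate@censored, ")")
  n0 <- spectrumLevel(noise)
  new("CriticalRatio", value = estimate@threshold - n0,
      thresholdUsed = estimate@threshold, spectrumLevelUsed = n0)
}
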