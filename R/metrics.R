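#' @include synth.R
NULL

## Core P1/N1 scan on raw samples. A local maximum is a sample strictly
## greater than its predecessor and >= its successor (so a plateau is
## credited to its earliest sample, honouring "first peak" semantics);
## minima are the mirror image. P1 is the first local maximum in the
## search window exceeding +criterion, N1 the first local minimum after
## it below -criterion.
.scanPeaks <- function(x, times, from, to, criterion) {
  idx <- which(times >= from & times <= to)
  idx <- idx[idx > 1 & idx < length(x)]
  if (!length(idx)) return(NULL)
  v <- x[idx]
  isMax <- x[idx] > x[idx - 1L] & x[idx] >= x[idx + 1L]
  isMin <- x[idx] < x[idx - 1L] & x[idx] <= x[idx + 1L]
  p1 <- idx[isMax & v > criterion][1]
  if (is.na(p1)) return(NULL)
  after <- idx > p1
  n1 <- idx[after & isMin & v < -criterion][1]
  if (is.na(n1)) return(NULL)
  c(p1 = p1, n1 = n1)
}

#' Detect the first positive and negative ABR peaks
#'
#' Automates the "clear positive and negative peak" judgement: P1 is
#' the first local maximum inside the search window whose voltage
#' exceeds the prominence criterion, and N1 the first subsequent local
#' minimum falling below its negative. The criterion defaults to
#' `promFactor` times the baseline RMS estimated from the pre-onset
#' segment of the trace (trigger to sound-at-ear); pass `baselineRms`
#' to use a known noise floor instead. Optional moving-average
#' smoothing (`smoothWidth` samples) is applied before the scan;
#' default none.
#'
#' The trace is baseline-corrected first (the pre-onset mean is
#' subtracted), so results are invariant to a constant voltage offset.
#'
#' @param trace an [AbrTrace-class].
#' @param searchWindow numeric length-2, ms relative to the
#'   sound-at-ear onset; must lie inside the recording window.
#' @param promFactor prominence criterion in baseline-RMS units.
#' @param baselineRms known residual RMS, uV; `NULL` to estimate it
#'   from the pre-onset samples.
#' @param smoothWidth moving-average width in samples (0 = none).
#' @return an [AbrPeaks-class]; `found` is `FALSE` with NA fields when
#'   either peak is absent.
#' @examples
#' prof <- defaultSpeciesProfiles()$titmouse
#' tr <- simulateTrace(prof, TonePipSpec(2500, 60), quietCondition(),
#'                     seed = 1)
#' detectPeaks(tr)
#' @export
detectPeaks <- function(trace, searchWindow = c(0, 10), promFactor = 3,
                        baselineRms = NULL, smoothWidth = 0) {
  stopifnot(is(trace, "AbrTrace"), length(searchWindow) == 2)
  x <- trace@samples
  if (anyNA(x) || any(!is.finite(x)))
    stop("malformed trace: samples contain NA/NaN/Inf")
  n <- length(x)
  times <- trace@windowStart + (seq_len(n) - 1) / trace@sampleRate * 1000
  from <- trace@onset + searchWindow[1]
  to <- trace@onset + searchWindow[2]
  if (from < trace@windowStart || to > trace@windowEnd)
    stop("search window extends beyond the recording window")
  if (smoothWidth > 1)
    x <- as.numeric(stats::filter(x, rep(1 / smoothWidth, smoothWidth),
                                  sides = 2))
  pre <- x[times < trace@onset & !is.na(x)]
  if (length(pre) >= 5) x <- x - mean(pre)     # baseline correction
  if (is.null(baselineRms)) {
    if (length(pre) < 5)
      stop("no pre-onset segment to estimate the baseline from; supply 'baselineRms'")
    baselineRms <- sqrt(mean((pre - mean(pre))^2))
  }
  hit <- .scanPeaks(ifelse(is.na(x), 0, x), times, from, to,
                    promFactor * baselineRms)
  if (is.null(hit)) return(.notFoundPeaks())
  p1 <- hit["p1"]; n1 <- hit["n1"]
  new("AbrPeaks",
      p1Time = times[p1], p1Voltage = x[p1],
      n1Time = times[n1], n1Voltage = x[n1],
      amplitude = x[p1] - x[n1],
      latencyP1 = times[p1] - trace@onset,
      latencyN1 = times[n1] - trace@onset, found = TRUE)
}

#' @rdname AbrPeaks-class
#' @export
setMethod("found", "AbrPeaks", function(x) x@found)

#' ABR amplitude from a peak pair
#'
#' The voltage difference between the first positive and the first
#' negative peak, in uV.
#'
#' @param peaks an [AbrPeaks-class] with `found = TRUE`.
#' @return amplitude in uV.
#' @export
measureAmplitude <- function(peaks) {
  stopifnot(is(peaks, "AbrPeaks"))
  if (!peaks@found)
    stop("missing response: no peaks were found in this trace")
  peaks@p1Voltage - peaks@n1Voltage
}

#' Average two replicate traces
#'
#' Sample-wise mean of two traces recorded under identical conditions
#' (all metadata equal except the replicate id); epoch counts add.
#'
#' @param trace1,trace2 [AbrTrace-class] replicates of one condition.
#' @return an [AbrTrace-class] with `replicate = NA`.
#' @export
averageReplicates <- function(trace1, trace2) {
  stopifnot(is(trace1, "AbrTrace"), is(trace2, "AbrTrace"))
  same <- isTRUE(all.equal(trace1@sampleRate, trace2@sampleRate)) &&
    trace1@windowStart == trace2@windowStart &&
    trace1@windowEnd == trace2@windowEnd &&
    trace1@onset == trace2@onset &&
    trace1@subjectId == trace2@subjectId &&
    trace1@species == trace2@species &&
    identical(trace1@frequency, trace2@frequency) &&
    identical(trace1@level, trace2@level) &&
    identical(trace1@noise@isQuiet, trace2@noise@isQuiet) &&
    identical(trace1@noise@overallLevel, trace2@noise@overallLevel)
  if (!same)
    stop("pairing error: traces differ in more than the replicate id")
  out <- trace1
  out@samples <- (trace1@samples + trace2@samples) / 2
  out@nEpochs <- trace1@nEpochs + trace2@nEpochs
  out@replicate <- NA_integer_
  out
}

#' Click-response stability check
#'
#' Coefficient of variation of the evoked amplitude across a series of
#' click responses, used to monitor the physiological stability of a
#' subject during recording. The series is stable when the CV is at or
#' below `cvCutoff` and no amplitude lies more than `iqrK` interquartile
#' ranges outside the quartiles.
#'
#' @param peaksList list of [AbrPeaks-class]; entries with
#'   `found = FALSE` are dropped.
#' @param cvCutoff maximum acceptable CV.
#' @param iqrK outlier fence multiplier.
#' @return list with `cv`, `stable`, `n`, `outlier` (logical vector over
#'   the usable measurements).
#' @export
stabilityCheck <- function(peaksList, cvCutoff = 0.2, iqrK = 1.5) {
  amps <- vapply(peaksList, function(p) {
    if (is(p, "AbrPeaks") && p@found) p@amplitude else NA_real_
  }, numeric(1))
  amps <- amps[!is.na(amps)]
  if (length(amps) < 2)
    stop("insufficient data: need >= 2 measurements with detected peaks")
  cv <- sd(amps) / mean(amps)
  q <- quantile(amps, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- iqrK * (q[2] - q[1])
  outlier <- amps < q[1] - fence | amps > q[2] + fence
  list(cv = cv, stable = cv <= cvCutoff && !any(outlier),
       n = length(amps), outlier = outlier)
}
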