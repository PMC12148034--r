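#' @include AllClasses.R
NULL

#' Convert between overall level and spectrum level
#'
#' For flat band-limited noise the overall level \eqn{L_{ov}} (dB SPL)
#' and the spectrum level \eqn{N_0} (dB Hz^-1) are related by
#' \eqn{N_0 = L_{ov} - 10\log_{10}(\Delta f)} where \eqn{\Delta f} is
#' the bandwidth in Hz. Applied to a [NoiseCondition-class] the generics
#' return the stored levels instead.
#'
#' @param x an overall level in dB (for `spectrumLevel`), a spectrum
#'   level in dB Hz^-1 (for `overallLevel`), or a `NoiseCondition`.
#' @param bandwidth bandwidth in Hz (numeric methods only); must be > 0.
#' @return a level in dB Hz^-1 (`spectrumLevel`) or dB (`overallLevel`);
#'   NA for the quiet condition.
#' @examples
#' spectrumLevel(64, 6300)        # ~ 26 dB Hz^-1
#' overallLevel(spectrumLevel(64, 6300), 6300)  # 64, exact round trip
#' @export
setGeneric("spectrumLevel", function(x, ...) standardGeneric("spectrumLevel"))

#' @rdname spectrumLevel
#' @export
setGeneric("overallLevel", function(x, ...) standardGeneric("overallLevel"))

#' @rdname NoiseCondition-class
#' @param x a `NoiseCondition`.
#' @export
setGeneric("isQuiet", function(x) standardGeneric("isQuiet"))

#' @rdname AbrPeaks-class
#' @param x an `AbrPeaks`.
#' @export
setGeneric("found", function(x) standardGeneric("found"))

#' Equivalent rectangular bandwidth of an auditory filter
#'
#' Closed form \eqn{4 f_0 / p} for the symmetric roex(p) filter; equals
#' the integral of the filter's power weighting over frequency.
#'
#' @param filter a [RoexFilter-class].
#' @return bandwidth in Hz.
#' @examples
#' erbOf(RoexFilter(2000, p = 16))  # 500
#' @export
setGeneric("erbOf", function(filter) standardGeneric("erbOf"))

#' @rdname ThresholdEstimate-class
#' @param x a `ThresholdEstimate`.
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname ThresholdEstimate-class
#' @export
setGeneric("censored", function(x) standardGeneric("censored"))

#' @rdname AbrExperiment-class
#' @param x an `AbrExperiment`.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
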