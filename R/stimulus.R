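#' @include AllGenerics.R
NULL

## 4-term Blackman-Harris window (a0 - a1 cos + a2 cos - a3 cos form).
## At its centre sample (odd N) the coefficients sum to exactly 1, which
## lets the gate hand over to a unit plateau without a seam.
.blackmanHarris <- function(n) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- seq_len(n) - 1
  a[1] - a[2] * cos(2 * pi * k / (n - 1)) +
    a[3] * cos(4 * pi * k / (n - 1)) - a[4] * cos(6 * pi * k / (n - 1))
}

#' Synthesize a gated tone pip
#'
#' Returns the unit-amplitude pressure waveform of a tone pip whose
#' first and last `gateDuration` milliseconds are shaped by the rising
#' and falling halves of a 4-term Blackman-Harris window; the envelope
#' is exactly 1 on the plateau between the gates. The gates are counted
#' inside the total duration. Use [scaleToLevel()] to calibrate the
#' waveform to a sound pressure level.
#'
#' @param spec a [TonePipSpec-class].
#' @param sampleRate sampling rate, Hz; must be at least 4 times the
#'   carrier frequency.
#' @return numeric waveform of `round(duration/1000 * sampleRate)`
#'   samples, unit peak amplitude before level scaling.
#' @examples
#' w <- tonePip(TonePipSpec(2500, 60), 48000)  # 240 samples
#' length(w)
#' @seealso [bandNoise()] for the masker, [scaleToLevel()].
#' @export
tonePip <- function(spec, sampleRate = 48000) {
  stopifnot(is(spec, "TonePipSpec"))
  if (sampleRate < 4 * spec@frequency)
    stop("undersampled: 'sampleRate' must be >= 4 x the carrier frequency")
  n <- round(spec@duration / 1000 * sampleRate)
  g <- round(spec@gateDuration / 1000 * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  carrier <- sin(2 * pi * spec@frequency * t + spec@phase)
  env <- rep(1, n)
  if (g > 0) {
    w <- .blackmanHarris(2 * g + 1)   # centre sample (index g+1) is 1
    env[seq_len(g)] <- w[seq_len(g)]
    env[(n - g + 1):n] <- w[(g + 2):(2 * g + 1)]
  }
  carrier * env
}

#' Calibrate a unit waveform to a sound pressure level
#'
#' Scales a unit-amplitude sinusoidal waveform so that its plateau RMS
#' corresponds to `level` dB SPL re 20 uPa; the returned samples are in
#' pascals.
#'
#' @param wave numeric waveform with unit peak amplitude.
#' @param level target level, dB SPL.
#' @param reference reference pressure, Pa (20 uPa).
#' @return the scaled waveform.
#' @export
scaleToLevel <- function(wave, level, reference = 20e-6) {
  wave * sqrt(2) * reference * 10^(level / 20)
}

#' @rdname spectrumLevel
#' @param ... passed between methods.
#' @export
setMethod("spectrumLevel", "numeric", function(x, bandwidth) {
  if (any(bandwidth <= 0)) stop("'bandwidth' must be positive")
  x - 10 * log10(bandwidth)
})

#' @rdname spectrumLevel
#' @export
setMethod("spectrumLevel", "NoiseCondition", function(x) x@spectrumLevel)

#' @rdname spectrumLevel
#' @export
setMethod("overallLevel", "numeric", function(x, bandwidth) {
  if (any(bandwidth <= 0)) stop("'bandwidth' must be positive")
  x + 10 * log10(bandwidth)
})

#' @rdname spectrumLevel
#' @export
setMethod("overallLevel", "NoiseCondition", function(x) x@overallLevel)

#' @rdname NoiseCondition-class
#' @export
setMethod("isQuiet", "NoiseCondition", function(x) x@isQuiet)

#' Synthesize a band-limited flat-spectrum masker
#'
#' Generates Gaussian-like noise whose power spectrum is exactly flat
#' across the passband (every FFT bin in the band gets equal magnitude
#' and an independent random phase) and zero outside it, then calibrates
#' the waveform RMS to the condition's overall level (re 20 uPa; samples
#' in pascals). A `lowCut` of 0 starts synthesis at the first positive
#' frequency bin, since DC carries no acoustic meaning.
#'
#' @param condition a non-quiet [NoiseCondition-class].
#' @param duration seconds.
#' @param sampleRate Hz; must be at least twice the upper band edge.
#' @param seed optional integer for a reproducible waveform.
#' @return numeric waveform in pascals.
#' @examples
#' cond <- NoiseCondition(overallLevel = 64)
#' x <- bandNoise(cond, duration = 0.5, seed = 1)
#' 20 * log10(sqrt(mean(x^2)) / 20e-6)   # ~ 64 dB SPL
#' @export
bandNoise <- function(condition, duration, sampleRate = 48000, seed = NULL) {
  stopifnot(is(condition, "NoiseCondition"))
  if (isQuiet(condition))
    stop("no masker: the quiet condition has no noise waveform")
  if (sampleRate < 2 * condition@highCut)
    stop("'sampleRate' must be at least twice the upper band edge")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sampleRate)
  nyq <- floor((n - 1) / 2)            # positive bins below Nyquist
  binFreq <- (1:nyq) * sampleRate / n
  sel <- which(binFreq >= condition@lowCut & binFreq <= condition@highCut &
                 binFreq > 0)
  if (!length(sel)) stop("no FFT bins fall inside the passband")
  spec <- complex(length.out = n)
  spec[1 + sel] <- exp(1i * runif(length(sel), 0, 2 * pi))
  spec[n + 1 - sel] <- Conj(spec[1 + sel])
  x <- Re(fft(spec, inverse = TRUE)) / n
  target <- 20e-6 * 10^(condition@overallLevel / 20)
  x * target / sqrt(mean(x^2))
}
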