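#' @include stimulus.R
NULL

#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer: 16-bit integer PCM (samples expected in
#' [-1, 1]; values outside are clipped with a warning) or 32-bit IEEE
#' float (written as-is).
#'
#' @param samples numeric waveform.
#' @param path output file.
#' @param sampleRate Hz.
#' @param bitDepth 16 (integer PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, path, sampleRate = 48000, bitDepth = 16) {
  stopifnot(bitDepth %in% c(16, 32))
  n <- length(samples)
  bytes <- bitDepth / 8
  dataSize <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt <- if (bitDepth == 16) 1L else 3L      # PCM / IEEE float
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bitDepth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bitDepth == 16) {
    if (any(abs(samples) > 1)) {
      warning("samples outside [-1, 1] clipped for 16-bit output")
      samples <- pmin(1, pmax(-1, samples))
    }
    writeBin(as.integer(round(samples * 32767)), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a stimulus configuration block
#'
#' Parses a YAML file with a `stimulus:` block
#' (`frequencies_hz`, `levels_db`, `noise_conditions` each with
#' `overall_db` and `band_hz`, `sample_rate_hz`, `seed`) into tone-pip
#' specs and noise conditions.
#'
#' @param path YAML file.
#' @return list with `tonePips` (list of [TonePipSpec-class], one per
#'   frequency x level), `noiseConditions` (incl. the quiet condition),
#'   `sampleRate`, `seed`.
#' @export
readStimulusConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  st <- cfg$stimulus
  if (is.null(st)) stop("no 'stimulus:' block in ", path)
  pips <- list()
  for (f in st$frequencies_hz)
    for (lv in st$levels_db)
      pips[[length(pips) + 1L]] <- TonePipSpec(frequency = f, level = lv)
  conds <- list(quiet = quietCondition())
  for (nc in st$noise_conditions) {
    band <- nc$band_hz
    conds[[paste0("n", nc$overall_db)]] <-
      NoiseCondition(overallLevel = nc$overall_db,
                     lowCut = band[[1]], highCut = band[[2]])
  }
  list(tonePips = pips, noiseConditions = conds,
       sampleRate = st$sample_rate_hz %||% 48000, seed = st$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
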