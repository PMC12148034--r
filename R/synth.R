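#' @include stimulus.R
NULL

## Acoustic travel time from the overhead speaker to the ear, ms.
.travelMs <- function(distance = 0.5, speed = 343) distance / speed * 1000

.profileAt <- function(profile, frequency) {
  i <- match(frequency, profile@frequencies)
  if (is.na(i))
    stop(sprintf("frequency %g Hz is not on the profile grid of '%s'",
                 frequency, profile@name))
  list(quietThreshold = profile@quietThreshold[i],
       criticalRatio = profile@criticalRatio[i])
}

#' Effective (quiet + masked) detection threshold
#'
#' Combines a quiet threshold with the masked threshold implied by the
#' power-spectrum model of masking. In noise with spectrum level
#' \eqn{N_0} and a species/frequency critical ratio CR, the masked
#' component sits at \eqn{N_0 + CR} dB SPL and combines with the quiet
#' threshold by power summation:
#' \deqn{T = 10\log_{10}\left(10^{T_q/10} + 10^{(N_0+CR)/10}\right).}
#' In the quiet condition the quiet threshold is returned unchanged.
#' Because the masked term grows dB-for-dB with \eqn{N_0}, critical
#' ratios derived from these thresholds are independent of noise level
#' once the masked term dominates.
#'
#' @param quietThreshold dB SPL.
#' @param noise a [NoiseCondition-class].
#' @param criticalRatio dB.
#' @return threshold in dB SPL.
#' @examples
#' effectiveThreshold(5, NoiseCondition(spectrumLevel = 26), 26)  # ~ 52
#' effectiveThreshold(30, quietCondition(), 26)                   # 30
#' @export
effectiveThreshold <- function(quietThreshold, noise, criticalRatio) {
  stopifnot(is.finite(criticalRatio))
  if (isQuiet(noise)) return(quietThreshold)
  n0 <- spectrumLevel(noise)
  10 * log10(10^(quietThreshold / 10) + 10^((n0 + criticalRatio) / 10))
}

## Saturating amplitude growth and exponential latency decay with
## sensation level; zero evoked component at or below threshold.
.evokedParams <- function(profile, sensationLevel, onset) {
  if (sensationLevel <= 0)
    return(list(amplitude = 0, p1Time = NA_real_, n1Time = NA_real_))
  a <- profile@amplitudeMax *
    (1 - exp(-sensationLevel / profile@amplitudeGrowth))
  lat <- profile@latencyMin +
    profile@latencySpan * exp(-sensationLevel / profile@latencyLevelConstant)
  list(amplitude = a, p1Time = onset + lat,
       n1Time = onset + lat + profile@interpeakInterval)
}

## Two opposite-signed Gaussian pulses reproduce the P1/N1 morphology.
.evokedWaveform <- function(times, params, pulseSd) {
  if (params$amplitude == 0) return(numeric(length(times)))
  half <- params$amplitude / 2
  half * exp(-(times - params$p1Time)^2 / (2 * pulseSd^2)) -
    half * exp(-(times - params$n1Time)^2 / (2 * pulseSd^2))
}

#' Simulate one averaged ABR trace
#'
#' Deterministic P1/N1 component (two opposite-signed Gaussian pulses)
#' plus additive Gaussian residual noise with RMS
#' `epochNoiseRms / sqrt(nEpochs)`, emulating an average of `nEpochs`
#' raw epochs. Peak-to-peak amplitude grows with sensation level as
#' \eqn{A_{max}(1 - e^{-SL/\tau_A})} and the P1 latency decays as
#' \eqn{L_{min} + L_{span} e^{-SL/\tau_L}}, offset by the acoustic
#' travel time from the speaker (0.5 m by default). At or below the
#' effective threshold the trace is pure residual noise.
#'
#' An optional cochlear-microphonic component (`cmAmplitude` > 0) adds a
#' stimulus-following sinusoid that inverts with the pip's starting
#' phase, so it cancels when phase-0 and phase-pi averages are combined.
#'
#' @param profile a [SpeciesProfile-class].
#' @param spec a [TonePipSpec-class] (its `level` is the stimulus level).
#' @param noise a [NoiseCondition-class].
#' @param subjectOffset subject-specific quiet-threshold offset, dB.
#' @param replicate replicate id, 1 or 2.
#' @param nEpochs epochs averaged into the trace.
#' @param epochNoiseRms single-epoch residual EEG RMS, uV.
#' @param sampleRate,windowStart,windowEnd acquisition window (Hz, ms).
#' @param subjectId label for the trace.
#' @param speakerDistance,soundSpeed acoustic travel geometry (m, m/s).
#' @param pulseSd Gaussian pulse SD, ms.
#' @param cmAmplitude cochlear-microphonic amplitude, uV (0 = off).
#' @param seed optional integer; the caller may instead manage the RNG
#'   stream and draw replicates sequentially.
#' @return an [AbrTrace-class].
#' @export
simulateTrace <- function(profile, spec, noise, subjectOffset = 0,
                          replicate = 1L, nEpochs = 400, epochNoiseRms = 2,
                          sampleRate = 24000, windowStart = 0,
                          windowEnd = 12, subjectId = profile@name,
                          speakerDistance = 0.5, soundSpeed = 343,
                          pulseSd = 0.17, cmAmplitude = 0, seed = NULL) {
  stopifnot(is(profile, "SpeciesProfile"), is(spec, "TonePipSpec"),
            nEpochs >= 1)
  if (!is.null(seed)) set.seed(seed)
  onset <- .travelMs(speakerDistance, soundSpeed)
  at <- .profileAt(profile, spec@frequency)
  eff <- effectiveThreshold(at$quietThreshold + subjectOffset, noise,
                            at$criticalRatio)
  sl <- spec@level - eff
  n <- round((windowEnd - windowStart) / 1000 * sampleRate)
  times <- windowStart + (seq_len(n) - 1) / sampleRate * 1000
  params <- .evokedParams(profile, sl, onset)
  x <- .evokedWaveform(times, params, pulseSd)
  if (cmAmplitude > 0 && sl > -20) {
    inPip <- times >= onset & times <= onset + spec@duration
    x[inPip] <- x[inPip] + cmAmplitude *
      sin(2 * pi * spec@frequency * (times[inPip] - onset) / 1000 +
            spec@phase)
  }
  x <- x + rnorm(n, 0, epochNoiseRms / sqrt(nEpochs))
  new("AbrTrace", samples = x, sampleRate = sampleRate,
      windowStart = windowStart, windowEnd = windowEnd, onset = onset,
      subjectId = subjectId, species = profile@name,
      frequency = spec@frequency, level = spec@level, noise = noise,
      replicate = as.integer(replicate), nEpochs = as.integer(nEpochs))
}

#' Default masking-noise conditions
#'
#' The quiet condition plus flat 0-6.3 kHz maskers at overall levels of
#' 44, 54 and 64 dB, i.e. spectrum levels of about 6, 16 and 26
#' dB Hz^-1.
#'
#' @param lowCut,highCut band edges, Hz.
#' @return named list of [NoiseCondition-class] objects.
#' @export
defaultNoiseConditions <- function(lowCut = 0, highCut = 6300) {
  list(quiet = quietCondition(lowCut, highCut),
       n6 = NoiseCondition(overallLevel = 44, lowCut = lowCut, highCut = highCut),
       n16 = NoiseCondition(overallLevel = 54, lowCut = lowCut, highCut = highCut),
       n26 = NoiseCondition(overallLevel = 64, lowCut = lowCut, highCut = highCut))
}

#' Default species simulation profiles
#'
#' Three songbird profiles on the 1-4 kHz grid encoding the qualitative
#' structure the analysis is built to resolve: the nuthatch has the
#' lowest quiet thresholds but the highest critical ratios, the titmouse
#' the lowest critical ratios, the chickadee is intermediate, and
#' critical-ratio differences are confined to frequencies at or above
#' 2.5 kHz. Values are configuration, not measurements.
#'
#' @return named list of [SpeciesProfile-class] objects.
#' @export
defaultSpeciesProfiles <- function() {
  f <- c(1000, 2000, 2500, 3150, 4000)
  list(
    chickadee = SpeciesProfile("chickadee", f,
      quietThreshold = c(38, 26, 22, 24, 30),
      criticalRatio = c(28, 25, 27, 28, 29)),
    titmouse = SpeciesProfile("titmouse", f,
      quietThreshold = c(34, 22, 18, 20, 26),
      criticalRatio = c(28, 25, 24, 25, 26)),
    nuthatch = SpeciesProfile("nuthatch", f,
      quietThreshold = c(30, 18, 14, 16, 22),
      criticalRatio = c(28, 25, 30, 31, 32))
  )
}

## Stimulus-level grid centred on an expected threshold: 5-dB steps
## within +-10 dB of it, 10-dB steps up to the 60 dB ceiling -- the
## "smaller steps near threshold" presentation scheme.
.levelGrid <- function(expected, maxLevel = 60, minLevel = 5,
                       fineStep = 5, fineHalf = 10, coarseStep = 10) {
  lo <- max(minLevel, fineStep * floor((expected - fineHalf) / fineStep))
  hi <- min(maxLevel, fineStep * ceiling((expected + fineHalf) / fineStep))
  lv <- seq(lo, hi, by = fineStep)
  if (max(lv) < maxLevel)
    lv <- c(lv, seq(min(max(lv) + coarseStep, maxLevel), maxLevel,
                    by = coarseStep))
  sort(unique(c(lv, maxLevel)), decreasing = TRUE)
}

#' Simulate a complete ABR experiment
#'
#' Generates two replicate averaged traces for every subject x
#' frequency x noise condition x stimulus level cell, together with a
#' ground-truth manifest of every drawn threshold. Per-subject quiet
#' thresholds are the species profile values plus one
#' Normal(0, `subjectSd`) offset per subject; masked thresholds follow
#' [effectiveThreshold()]. Stimulus levels default to a grid with 5-dB
#' steps near the (species-median) expected threshold and coarser
#' 10-dB steps up to 60 dB SPL, mirroring standard ABR practice.
#'
#' @param profiles list of [SpeciesProfile-class].
#' @param nSubjects integer vector, subjects per species (recycled
#'   against `profiles`).
#' @param frequencies stimulus frequencies, Hz.
#' @param noiseConditions named list of [NoiseCondition-class].
#' @param levels `NULL` for the automatic grid, a numeric vector used
#'   everywhere, or `function(frequency, noise)` returning the grid.
#' @param nEpochs,epochNoiseRms,sampleRate,windowStart,windowEnd,speakerDistance,soundSpeed,pulseSd
#'   passed to [simulateTrace()].
#' @param subjectIds optional list (per species) of subject labels;
#'   duplicated ids are an error.
#' @param seed integer; the whole experiment is reproducible from it.
#' @return an [AbrExperiment-class]; `groundTruth()` returns the
#'   per-subject true thresholds, and `metadata()$conditionTruth` the
#'   per-condition true amplitudes and latencies.
#' @examples
#' profs <- defaultSpeciesProfiles()["titmouse"]
#' ae <- simulateExperiment(profs, nSubjects = 2,
#'   frequencies = 2500, noiseConditions = defaultNoiseConditions()[1:2],
#'   seed = 1)
#' ae
#' @export
simulateExperiment <- function(profiles, nSubjects,
                               frequencies = c(1000, 2000, 2500, 3150, 4000),
                               noiseConditions = defaultNoiseConditions(),
                               levels = NULL, nEpochs = 400,
                               epochNoiseRms = 2, sampleRate = 24000,
                               windowStart = 0, windowEnd = 12,
                               speakerDistance = 0.5, soundSpeed = 343,
                               pulseSd = 0.17, subjectIds = NULL,
                               seed = 1) {
  stopifnot(length(profiles) >= 1, length(frequencies) >= 1,
            length(noiseConditions) >= 1)
  nSubjects <- rep_len(nSubjects, length(profiles))
  set.seed(seed)
  onset <- .travelMs(speakerDistance, soundSpeed)
  if (is.null(names(noiseConditions)))
    names(noiseConditions) <- paste0("nc", seq_along(noiseConditions))

  levelsFor <- function(frequency, noise) {
    if (is.numeric(levels)) return(sort(levels, decreasing = TRUE))
    if (is.function(levels)) return(sort(levels(frequency, noise),
                                         decreasing = TRUE))
    expected <- stats::median(vapply(profiles, function(p) {
      at <- .profileAt(p, frequency)
      effectiveThreshold(at$quietThreshold, noise, at$criticalRatio)
    }, numeric(1)))
    .levelGrid(expected)
  }

  ## subject labels and threshold offsets (one draw per subject)
  subjects <- list()
  for (i in seq_along(profiles)) {
    ids <- if (!is.null(subjectIds)) subjectIds[[i]] else
      sprintf("%s_%02d", profiles[[i]]@name, seq_len(nSubjects[i]))
    offs <- rnorm(nSubjects[i], 0, profiles[[i]]@subjectSd)
    subjects[[i]] <- data.frame(subject_id = ids, offset = offs,
                                stringsAsFactors = FALSE)
  }
  allIds <- unlist(lapply(subjects, `[[`, "subject_id"))
  if (anyDuplicated(allIds)) stop("duplicate subject ids in the design")

  nSamp <- round((windowEnd - windowStart) / 1000 * sampleRate)
  times <- windowStart + (seq_len(nSamp) - 1) / sampleRate * 1000
  traceRms <- epochNoiseRms / sqrt(nEpochs)

  cols <- list(); meta <- list(); truth <- list(); condTruth <- list()
  k <- 0L
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    for (s in seq_len(nrow(subjects[[i]]))) {
      sid <- subjects[[i]]$subject_id[s]
      off <- subjects[[i]]$offset[s]
      for (f in frequencies) {
        at <- .profileAt(prof, f)
        for (nc in names(noiseConditions)) {
          noise <- noiseConditions[[nc]]
          eff <- effectiveThreshold(at$quietThreshold + off, noise,
                                    at$criticalRatio)
          truth[[length(truth) + 1L]] <- data.frame(
            subject_id = sid, species = prof@name, frequency_hz = f,
            noise_class = nc,
            noise_spectrum_db = if (isQuiet(noise)) NA_real_ else
              spectrumLevel(noise),
            true_threshold_db = eff, stringsAsFactors = FALSE)
          for (lv in levelsFor(f, noise)) {
            params <- .evokedParams(prof, lv - eff, onset)
            det <- .evokedWaveform(times, params, pulseSd)
            condTruth[[length(condTruth) + 1L]] <- data.frame(
              subject_id = sid, species = prof@name, frequency_hz = f,
              noise_class = nc, level_db = lv,
              true_amplitude_uv = params$amplitude,
              true_latency_p1_ms = if (is.na(params$p1Time)) NA_real_ else
                params$p1Time - onset,
              true_latency_n1_ms = if (is.na(params$n1Time)) NA_real_ else
                params$n1Time - onset, stringsAsFactors = FALSE)
            for (rep_ in 1:2) {
              k <- k + 1L
              cols[[k]] <- det + rnorm(nSamp, 0, traceRms)
              meta[[k]] <- data.frame(
                subject_id = sid, species = prof@name, frequency_hz = f,
                level_db = lv,
                noise_overall_db = if (isQuiet(noise)) NA_real_ else
                  overallLevel(noise),
                noise_spectrum_db = if (isQuiet(noise)) NA_real_ else
                  spectrumLevel(noise),
                is_quiet = isQuiet(noise), noise_class = nc,
                replicate = rep_, n_epochs = nEpochs,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }

  assay <- do.call(cbind, cols)
  cd <- do.call(rbind, meta)
  colnames(assay) <- sprintf("trace_%05d", seq_len(ncol(assay)))
  rownames(cd) <- colnames(assay)
  band <- c(noiseConditions[[1]]@lowCut, noiseConditions[[1]]@highCut)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(voltage = assay),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(sampleRate = sampleRate, windowStart = windowStart,
                    windowEnd = windowEnd, onset = onset,
                    noiseBand = band, epochNoiseRms = epochNoiseRms,
                    pulseSd = pulseSd, seed = seed,
                    groundTruth = do.call(rbind, truth),
                    conditionTruth = do.call(rbind, condTruth),
                    profiles = profiles,
                    noiseConditions = noiseConditions))
  new("AbrExperiment", se)
}

#' Simulate a click-response stability series
#'
#' Click-evoked traces recorded at several time points with a constant
#' deterministic component; `drift` < 1 scales the evoked amplitude
#' linearly down to that fraction by the last time point, for testing
#' instability detection.
#'
#' @param profile a [SpeciesProfile-class].
#' @param times numeric vector of at least two recording time points
#'   (arbitrary units; only their number and order matter).
#' @param drift amplitude factor reached at the last time point.
#' @param level click level, dB SPL.
#' @inheritParams simulateTrace
#' @return list of [AbrTrace-class] (frequency slot 0 marks a click).
#' @export
simulateClickSeries <- function(profile, times, drift = 1, level = 60,
                                subjectId = profile@name,
                                noise = quietCondition(), nEpochs = 400,
                                epochNoiseRms = 2, sampleRate = 24000,
                                windowStart = 0, windowEnd = 12,
                                speakerDistance = 0.5, soundSpeed = 343,
                                pulseSd = 0.17, seed = NULL) {
  if (length(times) < 2) stop("a stability series needs >= 2 time points")
  if (!is.null(seed)) set.seed(seed)
  onset <- .travelMs(speakerDistance, soundSpeed)
  n <- round((windowEnd - windowStart) / 1000 * sampleRate)
  tAxis <- windowStart + (seq_len(n) - 1) / sampleRate * 1000
  factors <- seq(1, drift, length.out = length(times))
  lapply(seq_along(times), function(i) {
    params <- list(amplitude = profile@amplitudeMax * factors[i],
                   p1Time = onset + profile@latencyMin,
                   n1Time = onset + profile@latencyMin +
                     profile@interpeakInterval)
    x <- .evokedWaveform(tAxis, params, pulseSd) +
      rnorm(n, 0, epochNoiseRms / sqrt(nEpochs))
    new("AbrTrace", samples = x, sampleRate = sampleRate,
        windowStart = windowStart, windowEnd = windowEnd, onset = onset,
        subjectId = subjectId, species = profile@name, frequency = 0,
        level = level, noise = noise, replicate = 1L,
        nEpochs = as.integer(nEpochs))
  })
}

#' Desk-scale critical-ratio table generator
#'
#' Draws per-subject critical ratios directly (species profile value +
#' one Normal(0, `subjectSd`) subject intercept + Normal(0,
#' `residualSd`) cell residual) without waveform synthesis. Used for
#' Monte-Carlo calibration of the mixed-model analysis, where hundreds
#' of replicate experiments are needed; the residual SD defaults to the
#' SD of the quantisation error of a 5-dB level grid (~1.5 dB).
#'
#' @param profiles list of [SpeciesProfile-class].
#' @param nSubjects subjects per species (recycled).
#' @param frequencies Hz, must lie on the profile grids.
#' @param spectrumLevels masker spectrum levels, dB Hz^-1.
#' @param subjectSd between-subject SD of critical ratios, dB; default
#'   takes each profile's `subjectSd`.
#' @param residualSd within-cell measurement SD, dB.
#' @param seed integer.
#' @return data.frame with columns `subject_id`, `species`,
#'   `frequency_hz`, `noise_spectrum_db`, `cr_db`, `threshold_db`.
#' @export
simulateCrTable <- function(profiles, nSubjects, frequencies = c(2500, 3150, 4000),
                            spectrumLevels = c(6, 16, 26),
                            subjectSd = NULL, residualSd = 1.5, seed = 1) {
  nSubjects <- rep_len(nSubjects, length(profiles))
  set.seed(seed)
  out <- list()
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    sdS <- if (is.null(subjectSd)) prof@subjectSd else subjectSd
    for (s in seq_len(nSubjects[i])) {
      sid <- sprintf("%s_%02d", prof@name, s)
      u <- rnorm(1, 0, sdS)
      for (f in frequencies) {
        cr0 <- .profileAt(prof, f)$criticalRatio
        for (n0 in spectrumLevels) {
          cr <- cr0 + u + rnorm(1, 0, residualSd)
          out[[length(out) + 1L]] <- data.frame(
            subject_id = sid, species = prof@name, frequency_hz = f,
            noise_spectrum_db = n0, cr_db = cr, threshold_db = n0 + cr,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' @rdname AbrExperiment-class
#' @export
setMethod("groundTruth", "AbrExperiment", function(x)
  S4Vectors::metadata(x)$groundTruth)

#' Extract one trace from an AbrExperiment
#'
#' @param x an [AbrExperiment-class].
#' @param i column index or trace name.
#' @return an [AbrTrace-class].
#' @export
getTrace <- function(x, i) {
  stopifnot(is(x, "AbrExperiment"))
  cd <- SummarizedExperiment::colData(x)[i, , drop = FALSE]
  m <- S4Vectors::metadata(x)
  noise <- if (cd$is_quiet)
    quietCondition(m$noiseBand[1], m$noiseBand[2])
  else
    NoiseCondition(overallLevel = cd$noise_overall_db,
                   spectrumLevel = cd$noise_spectrum_db,
                   lowCut = m$noiseBand[1], highCut = m$noiseBand[2])
  new("AbrTrace",
      samples = as.numeric(SummarizedExperiment::assay(x, "voltage")[, i]),
      sampleRate = m$sampleRate, windowStart = m$windowStart,
      windowEnd = m$windowEnd, onset = m$onset,
      subjectId = cd$subject_id, species = cd$species,
      frequency = cd$frequency_hz, level = cd$level_db, noise = noise,
      replicate = as.integer(cd$replicate),
      nEpochs = as.integer(cd$n_epochs))
}

#' Time axis of the traces in an AbrExperiment
#'
#' @param x an [AbrExperiment-class].
#' @return sample times in ms relative to the playback trigger.
#' @export
traceTimes <- function(x) {
  m <- S4Vectors::metadata(x)
  n <- nrow(x)
  m$windowStart + (seq_len(n) - 1) / m$sampleRate * 1000
}
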