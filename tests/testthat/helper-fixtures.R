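# Shared fixtures: small profiles and an independent brute-force peak
# scanner used as the oracle for detectPeaks().

makeProfile <- function(name = "testbird", quiet = 20, cr = 26,
                        frequencies = 2500, subjectSd = 0, ...) {
  SpeciesProfile(name, frequencies,
                 quietThreshold = rep(quiet, length(frequencies)),
                 criticalRatio = rep(cr, length(frequencies)),
                 subjectSd = subjectSd, ...)
}

# First local max above +criterion, then first subsequent local min
# below -criterion, by exhaustive per-sample scan. Mirrors the
# documented extremum rule (plateaus credited to their first sample)
# but shares no code with the package implementation.
bruteForcePeaks <- function(x, times, from, to, criterion) {
  p1 <- NA_integer_
  for (i in 2:(length(x) - 1)) {
    if (times[i] < from || times[i] > to) next
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] > criterion) {
      p1 <- i; break
    }
  }
  if (is.na(p1)) return(NULL)
  n1 <- NA_integer_
  for (i in (p1 + 1):(length(x) - 1)) {
    if (times[i] > to) break
    if (x[i] < x[i - 1] && x[i] <= x[i + 1] && x[i] < -criterion) {
      n1 <- i; break
    }
  }
  if (is.na(n1)) return(NULL)
  c(p1 = p1, n1 = n1)
}

# Wrap raw samples in an AbrTrace at 24 kHz, 0-12 ms, onset ~1.458 ms.
wrapTrace <- function(samples, sampleRate = 24000, windowEnd = 12,
                      onset = 0.5 / 343 * 1000) {
  new("AbrTrace", samples = samples, sampleRate = sampleRate,
      windowStart = 0, windowEnd = windowEnd, onset = onset,
      subjectId = "s1", species = "testbird", frequency = 2500,
      level = 60, noise = quietCondition(), replicate = 1L,
      nEpochs = 400L)
}
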