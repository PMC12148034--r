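test_that("peaks of a clean synthetic trace are located and measured", {
  # P1 at 3.0 ms and N1 at 4.0 ms post-onset, peak-to-peak 2 uV
  prof <- makeProfile(quiet = 20, latencyMin = 3, latencySpan = 0,
                      interpeakInterval = 1, amplitudeMax = 2,
                      amplitudeGrowth = 1e-6)
  tr <- simulateTrace(prof, TonePipSpec(2500, 60), quietCondition(),
                      epochNoiseRms = 0)
  pk <- detectPeaks(tr, baselineRms = 0.01)
  expect_true(found(pk))
  expect_equal(pk@latencyP1, 3.0, tolerance = 0.05)
  expect_equal(pk@latencyN1, 4.0, tolerance = 0.05)
  expect_equal(pk@amplitude, 2, tolerance = 0.05)
  expect_equal(measureAmplitude(pk), pk@p1Voltage - pk@n1Voltage)
})

test_that("pure-noise traces rarely pass the 3x-RMS criterion", {
  set.seed(91)
  n <- round(12 / 1000 * 24000)
  hits <- replicate(500, {
    tr <- wrapTrace(rnorm(n, 0, 0.1))
    found(detectPeaks(tr, promFactor = 3, baselineRms = 0.1))
  })
  expect_lte(mean(hits), 0.05)
})

test_that("polarity inversion breaks the P1-before-N1 ordering", {
  prof <- makeProfile(quiet = 20, latencyMin = 3, latencySpan = 0)
  tr <- simulateTrace(prof, TonePipSpec(2500, 60), quietCondition(),
                      epochNoiseRms = 0)
  pk <- detectPeaks(tr, baselineRms = 0.01)
  trNeg <- tr
  trNeg@samples <- -tr@samples
  pkNeg <- detectPeaks(trNeg, baselineRms = 0.01)
  expect_true(!found(pkNeg) ||
                !isTRUE(all.equal(pkNeg@p1Time, pk@p1Time)))
})

test_that("amplitude errors on a missing response", {
  tr <- wrapTrace(rep(0, 288))
  pk <- detectPeaks(tr, baselineRms = 0.1)
  expect_false(found(pk))
  expect_error(measureAmplitude(pk), "missing response")
})

test_that("NaN samples are rejected", {
  x <- rep(0, 288); x[10] <- NaN
  expect_error(detectPeaks(wrapTrace(x), baselineRms = 0.1), "malformed")
})

test_that("peak measures are invariant to a constant voltage offset", {
  prof <- makeProfile(quiet = 20)
  tr <- simulateTrace(prof, TonePipSpec(2500, 55), quietCondition(),
                      seed = 14)
  pk <- detectPeaks(tr)
  shifted <- tr
  shifted@samples <- tr@samples + 7.5
  pk2 <- detectPeaks(shifted)
  expect_equal(pk2@amplitude, pk@amplitude)
  expect_equal(pk2@latencyP1, pk@latencyP1)
  expect_equal(pk2@latencyN1, pk@latencyN1)
})

test_that("latencies never precede the acoustic travel delay", {
  set.seed(55)
  prof <- makeProfile(quiet = 20)
  for (i in 1:20) {
    tr <- simulateTrace(prof, TonePipSpec(2500, sample(10:60, 1)),
                        quietCondition())
    pk <- detectPeaks(tr)
    if (found(pk)) {
      expect_gte(pk@latencyP1, 0)
      expect_gte(pk@p1Time, tr@onset)
    }
  }
})

test_that("detectPeaks agrees exactly with the brute-force scan", {
  set.seed(77)
  n <- round(12 / 1000 * 24000)
  onset <- 0.5 / 343 * 1000
  times <- (seq_len(n) - 1) / 24000 * 1000
  for (i in 1:200) {
    x <- rnorm(n, 0, 0.3)
    if (i %% 2 == 0) {   # half the traces carry an evoked-like pulse pair
      t1 <- runif(1, 2, 6); a <- runif(1, 0.3, 2)
      x <- x + a * exp(-(times - t1)^2 / 0.08) -
        a * exp(-(times - t1 - 1)^2 / 0.08)
    }
    x <- x - mean(x[times < onset])   # same baseline correction
    expected <- bruteForcePeaks(x, times, onset, onset + 10, 3 * 0.3)
    got <- detectPeaks(wrapTrace(x), baselineRms = 0.3)
    if (is.null(expected)) {
      expect_false(found(got))
    } else {
      expect_true(found(got))
      expect_equal(got@p1Time, times[expected["p1"]])
      expect_equal(got@n1Time, times[expected["n1"]])
    }
  }
})

test_that("replicate averaging is a sample-wise mean with summed epochs", {
  prof <- makeProfile(quiet = 20)
  spec <- TonePipSpec(2500, 60)
  set.seed(3)
  tr1 <- simulateTrace(prof, spec, quietCondition(), replicate = 1)
  tr2 <- simulateTrace(prof, spec, quietCondition(), replicate = 2)
  avg <- averageReplicates(tr1, tr2)
  expect_equal(avg@samples, (tr1@samples + tr2@samples) / 2)
  expect_identical(avg@nEpochs, 800L)
  expect_true(is.na(avg@replicate))
  # idempotent on identical traces, cancels on negation
  expect_equal(averageReplicates(tr1, tr1)@samples, tr1@samples)
  neg <- tr1; neg@samples <- -tr1@samples; neg@replicate <- 2L
  expect_equal(max(abs(averageReplicates(tr1, neg)@samples)), 0)
  # metadata mismatch is a pairing error
  other <- simulateTrace(prof, TonePipSpec(2500, 40), quietCondition())
  expect_error(averageReplicates(tr1, other), "pairing")
})

test_that("averaging two replicates shrinks residual RMS by sqrt(2)", {
  prof <- makeProfile(quiet = 20)
  spec <- TonePipSpec(2500, 5)      # subthreshold: pure residual
  set.seed(21)
  ratio <- replicate(100, {
    tr1 <- simulateTrace(prof, spec, quietCondition(), replicate = 1)
    tr2 <- simulateTrace(prof, spec, quietCondition(), replicate = 2)
    avg <- averageReplicates(tr1, tr2)
    sqrt(mean(avg@samples^2)) / sqrt(mean(tr1@samples^2))
  })
  expect_equal(mean(ratio), 1 / sqrt(2), tolerance = 0.05)
})

test_that("stability check computes CV and flags outliers", {
  mk <- function(a) new("AbrPeaks", p1Time = 3, p1Voltage = a / 2,
                        n1Time = 4, n1Voltage = -a / 2, amplitude = a,
                        latencyP1 = 1.5, latencyN1 = 2.5, found = TRUE)
  const <- stabilityCheck(list(mk(2), mk(2), mk(2)))
  expect_equal(const$cv, 0)
  expect_true(const$stable)
  triple <- stabilityCheck(list(mk(2), mk(2), mk(1)))
  expect_equal(triple$cv, sd(c(2, 2, 1)) / mean(c(2, 2, 1)))
  expect_error(stabilityCheck(list(mk(2))), "insufficient")
  expect_error(stabilityCheck(list(mk(2), .crmaskNotFound <- local({
    p <- mk(1); p@found <- FALSE; p
  }))), "insufficient")
})
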