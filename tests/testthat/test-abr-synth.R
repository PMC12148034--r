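test_that("effective threshold follows the power-sum model", {
  n26 <- NoiseCondition(spectrumLevel = 26)
  # masked term dominates by 47 dB
  expect_equal(effectiveThreshold(5, n26, 26), 52, tolerance = 1e-3)
  # quiet identity
  expect_identical(effectiveThreshold(30, quietCondition(), 26), 30)
  # equal-power sum adds 10*log10(2)
  n0 <- NoiseCondition(spectrumLevel = 10)
  expect_equal(effectiveThreshold(36, n0, 26), 36 + 10 * log10(2))
})

test_that("masked thresholds grow dB-for-dB with spectrum level", {
  # slope-one property where the masked term dominates; the exact
  # power-sum slope is m/(m+q), i.e. 10/11 at 10 dB dominance, so the
  # 0.05-dB band is checked from 13 dB dominance upward
  for (tq in c(5, 15, 25)) {
    for (n0 in seq(tq - 16, tq + 10, by = 2)) {
      cond1 <- NoiseCondition(spectrumLevel = n0)
      cond2 <- NoiseCondition(spectrumLevel = n0 + 1)
      slope <- effectiveThreshold(tq, cond2, 26) -
        effectiveThreshold(tq, cond1, 26)
      if (n0 + 26 >= tq + 13) expect_lt(abs(slope - 1), 0.05)
    }
  }
})

test_that("subthreshold traces are pure residual noise with the 1/sqrt(n) floor", {
  prof <- makeProfile(quiet = 20)
  spec <- TonePipSpec(2500, 5)    # far below threshold
  set.seed(31)
  rms <- replicate(60, {
    tr <- simulateTrace(prof, spec, quietCondition(), nEpochs = 400,
                        epochNoiseRms = 2)
    sqrt(mean(tr@samples^2))
  })
  expect_equal(mean(rms), 2 / sqrt(400), tolerance = 0.05)
})

test_that("averaged-trace residual scales as 1/sqrt(nEpochs)", {
  prof <- makeProfile(quiet = 20)
  spec <- TonePipSpec(2500, 5)
  set.seed(32)
  meanRms <- vapply(c(100, 400, 1600), function(ne) {
    mean(replicate(50, {
      tr <- simulateTrace(prof, spec, quietCondition(), nEpochs = ne,
                          epochNoiseRms = 2)
      sqrt(mean(tr@samples^2))
    }))
  }, numeric(1))
  expect_equal(meanRms / (2 / sqrt(c(100, 400, 1600))), rep(1, 3),
               tolerance = 0.05)
})

test_that("evoked amplitude grows and latency shrinks with level", {
  prof <- makeProfile(quiet = 20)
  quiet <- quietCondition()
  peaksAt <- function(sl) {
    tr <- simulateTrace(prof, TonePipSpec(2500, 20 + sl), quiet,
                        epochNoiseRms = 0)
    detectPeaks(tr, baselineRms = 0.01)
  }
  p10 <- peaksAt(10); p40 <- peaksAt(40)
  expect_gt(p40@amplitude, p10@amplitude)
  expect_lt(p40@latencyP1, p10@latencyP1)
  # monotone over the whole level grid, every default profile
  for (prof in defaultSpeciesProfiles()) {
    sl <- seq(2, 50, by = 4)
    amps <- vapply(sl, function(s)
      prof@amplitudeMax * (1 - exp(-s / prof@amplitudeGrowth)), numeric(1))
    lats <- vapply(sl, function(s)
      prof@latencyMin + prof@latencySpan *
        exp(-s / prof@latencyLevelConstant), numeric(1))
    expect_true(all(diff(amps) > 0))
    expect_true(all(diff(lats) < 0))
  }
})

test_that("replicates share the deterministic component, not the residual", {
  prof <- makeProfile(quiet = 20)
  spec <- TonePipSpec(2500, 60)
  set.seed(7)
  tr1 <- simulateTrace(prof, spec, quietCondition(), replicate = 1)
  tr2 <- simulateTrace(prof, spec, quietCondition(), replicate = 2)
  expect_false(identical(tr1@samples, tr2@samples))
  det1 <- simulateTrace(prof, spec, quietCondition(), epochNoiseRms = 0)
  det2 <- simulateTrace(prof, spec, quietCondition(), epochNoiseRms = 0)
  expect_identical(det1@samples, det2@samples)
})

test_that("cochlear microphonic inverts with phase and cancels in pairs", {
  prof <- makeProfile(quiet = 20)
  t0 <- simulateTrace(prof, TonePipSpec(2500, 60, phase = 0),
                      quietCondition(), epochNoiseRms = 0,
                      cmAmplitude = 0.5)
  tp <- simulateTrace(prof, TonePipSpec(2500, 60, phase = pi),
                      quietCondition(), epochNoiseRms = 0,
                      cmAmplitude = 0.5)
  noCm <- simulateTrace(prof, TonePipSpec(2500, 60), quietCondition(),
                        epochNoiseRms = 0)
  expect_false(isTRUE(all.equal(t0@samples, noCm@samples)))
  expect_equal((t0@samples + tp@samples) / 2, noCm@samples,
               tolerance = 1e-12)
})

test_that("experiment bookkeeping, determinism and ground truth hold", {
  profs <- defaultSpeciesProfiles()[c("titmouse", "nuthatch")]
  conds <- defaultNoiseConditions()[c("quiet", "n16", "n26")]
  lv <- c(60, 40, 30, 20)
  ae <- simulateExperiment(profs, nSubjects = c(2, 1),
                           frequencies = c(2000, 2500),
                           noiseConditions = conds, levels = lv,
                           epochNoiseRms = 0.5, seed = 5)
  expect_s4_class(ae, "AbrExperiment")
  expect_identical(ncol(ae), 3L * 2L * 3L * 4L * 2L)
  ae2 <- simulateExperiment(profs, nSubjects = c(2, 1),
                            frequencies = c(2000, 2500),
                            noiseConditions = conds, levels = lv,
                            epochNoiseRms = 0.5, seed = 5)
  expect_identical(assay(ae, "voltage"), assay(ae2, "voltage"))
  expect_identical(as.data.frame(colData(ae)), as.data.frame(colData(ae2)))

  gt <- groundTruth(ae)
  expect_identical(nrow(gt), 3L * 2L * 3L)
  # thresholds 10 dB apart between the 16 and 26 dB Hz-1 conditions
  # wherever the masked term dominates
  wide <- merge(gt[gt$noise_class == "n26", ],
                gt[gt$noise_class == "n16", ],
                by = c("subject_id", "frequency_hz"))
  expect_equal(wide$true_threshold_db.x - wide$true_threshold_db.y,
               rep(10, nrow(wide)), tolerance = 0.3)

  expect_error(simulateExperiment(profs, nSubjects = c(1, 1),
                                  frequencies = 2500,
                                  noiseConditions = conds["quiet"],
                                  levels = lv,
                                  subjectIds = list("dup", "dup"),
                                  seed = 1),
               "duplicate")
})

test_that("getTrace reconstructs a trace faithfully", {
  prof <- defaultSpeciesProfiles()["titmouse"]
  ae <- simulateExperiment(prof, 1, frequencies = 2500,
                           noiseConditions = defaultNoiseConditions()[c(1, 4)],
                           levels = c(60, 30), seed = 2)
  tr <- getTrace(ae, 1)
  expect_s4_class(tr, "AbrTrace")
  expect_identical(tr@samples, unname(assay(ae, "voltage")[, 1]))
  expect_identical(tr@level, colData(ae)$level_db[1])
  expect_identical(length(traceTimes(ae)), nrow(ae))
  expect_equal(diff(traceTimes(ae))[1], 1000 / 24000)
})

test_that("click series reflects drift and needs two time points", {
  prof <- makeProfile(quiet = 20)
  expect_error(simulateClickSeries(prof, times = 1), ">= 2")
  stable <- simulateClickSeries(prof, times = 1:6, drift = 1,
                                epochNoiseRms = 0.5, seed = 8)
  drifty <- simulateClickSeries(prof, times = 1:6, drift = 0.5,
                                epochNoiseRms = 0.5, seed = 8)
  cvOf <- function(series) {
    stabilityCheck(lapply(series, detectPeaks))$cv
  }
  expect_gt(cvOf(drifty), cvOf(stable))
})
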