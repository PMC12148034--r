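test_that("cell summaries compute mean and s.e.m. correctly", {
  d <- data.frame(species = "a", frequency_hz = 2000,
                  noise_spectrum_db = c(16, 16, 16, 26),
                  cr_db = c(10, 20, 30, 25))
  s <- summarizeCells(d, "cr_db")
  cell <- s[s$noise_class == "16", ]
  expect_equal(cell$mean, 20)
  expect_equal(cell$sd, 10)
  expect_equal(cell$sem, 10 / sqrt(3))
  single <- s[s$noise_class == "26", ]
  expect_true(is.na(single$sem))
  expect_true(single$flag_single)
})

test_that("species F statistic vanishes when species means are identical", {
  # balanced, deterministic: response depends on frequency only
  d <- expand.grid(subject_id = sprintf("s%02d", 1:6),
                   frequency_hz = c(2000, 4000),
                   noise_spectrum_db = c(16, 26),
                   stringsAsFactors = FALSE)
  num <- as.integer(sub("s", "", d$subject_id))
  d$species <- ifelse(num <= 3, "a", "b")
  # subject effects symmetric within species: species means exactly equal
  subjEff <- c(-0.01, 0, 0.01, -0.01, 0, 0.01)
  set.seed(5)
  d$cr_db <- 20 + 5 * (d$frequency_hz == 4000) + subjEff[num] +
    rnorm(nrow(d), 0, 1e-3)
  fit <- suppressMessages(suppressWarnings(
    fitMixedModel(d, "cr_db", fixed = c("species", "frequency"),
                  interactions = FALSE)))
  Fsp <- fit$anova[fit$anova$term == "species", "F value"]
  expect_lt(Fsp, 1)   # species explains (almost) nothing
  Ffr <- fit$anova[fit$anova$term == "frequency", "F value"]
  expect_gt(Ffr, 100)
})

test_that("log transform and input validation behave", {
  profs <- defaultSpeciesProfiles()
  d <- simulateCrTable(profs, c(4, 4, 4), seed = 2)
  fit <- suppressMessages(fitMixedModel(d, "cr_db", transform = "log",
                                        fixed = "species"))
  expect_identical(fit$transform, "log")
  expect_identical(fit$dfMethod, "Satterthwaite")
  dNeg <- d; dNeg$cr_db[1] <- -1
  expect_error(fitMixedModel(dNeg, "cr_db", transform = "log"), "positive")
  dOne <- d[d$subject_id %in% c("chickadee_01", "titmouse_01",
                                "nuthatch_01"), ]
  expect_error(fitMixedModel(dOne, "cr_db", fixed = "species"),
               ">= 2 subjects")
})

test_that("an 8 dB species offset is detected at the study's sample sizes", {
  base <- defaultSpeciesProfiles()
  nullProfs <- lapply(base, function(p) { p@criticalRatio[] <- 26; p })
  offProfs <- nullProfs
  offProfs$nuthatch@criticalRatio[] <- 34
  hits <- vapply(1:10, function(i) {
    d <- simulateCrTable(offProfs, c(7, 6, 4), subjectSd = 2,
                         seed = 400 + i)
    f <- suppressMessages(fitMixedModel(d, "cr_db", fixed = "species"))
    f$anova[f$anova$term == "species", "Pr(>F)"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pairwise contrasts are Bonferroni-scaled over all pairs", {
  d <- simulateCrTable(defaultSpeciesProfiles(), c(5, 5, 4), seed = 6)
  fit <- suppressMessages(fitMixedModel(d, "cr_db", fixed = "species"))
  pc <- pairwiseContrasts(fit, "species")
  expect_identical(nrow(pc), 3L)                      # C(3,2)
  expect_true(all(pc$p_bonferroni >= pc$p_raw))
  expect_equal(pc$p_bonferroni, pmin(1, 3 * pc$p_raw), tolerance = 1e-9)
})

test_that("well-separated species CRs yield all-pairs significance", {
  base <- makeProfile(frequencies = c(2500, 3150, 4000))
  mk <- function(name, cr) {
    p <- base; p@name <- name; p@criticalRatio[] <- cr; p
  }
  profs <- list(mk("titmouse", 22), mk("chickadee", 27), mk("nuthatch", 32))
  hits <- vapply(1:5, function(i) {
    d <- simulateCrTable(profs, c(6, 7, 4), subjectSd = 1.5,
                         seed = 900 + i)
    f <- suppressMessages(fitMixedModel(d, "cr_db", fixed = "species"))
    pc <- pairwiseContrasts(f, "species")
    all(pc$p_bonferroni < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("model reduction drops only non-significant interactions", {
  d <- simulateCrTable(defaultSpeciesProfiles(), c(5, 5, 4),
                       frequencies = c(2000, 2500, 4000), seed = 8)
  fit <- suppressMessages(fitMixedModel(d, "cr_db",
                                        fixed = c("species", "frequency",
                                                  "noise")))
  red <- suppressMessages(reduceModel(fit))
  expect_true(all(grepl(":", red$dropped)))
  expect_named(red$aic, c("full", "reduced"))
  # main effects survive
  expect_true(all(c("species", "frequency", "noise") %in%
                    red$reduced$anova$term))
})

test_that("marginal means equal cell means on balanced near-noiseless data", {
  d <- expand.grid(subject_id = sprintf("s%d", 1:4),
                   frequency_hz = c(2000, 4000), stringsAsFactors = FALSE)
  d$species <- ifelse(d$subject_id %in% c("s1", "s2"), "a", "b")
  d$cr_db <- 20 + 4 * (d$species == "b") + 2 * (d$frequency_hz == 4000)
  d$cr_db <- d$cr_db + rep(c(0.001, -0.001), 4)   # break exact singularity
  # near-noiseless data: convergence chatter is expected and harmless
  fit <- suppressWarnings(suppressMessages(
    fitMixedModel(d, "cr_db", fixed = c("species", "frequency"))))
  emm <- as.data.frame(emmeans::emmeans(fit$fit, ".species",
                                        lmer.df = "satterthwaite"))
  cellMeans <- tapply(d$cr_db, d$species, mean)
  expect_equal(as.numeric(emm$emmean),
               as.numeric(cellMeans[as.character(emm$.species)]),
               tolerance = 1e-6)
})

test_that("threshold-vs-noise slopes diagnose dB-for-dB masking", {
  d <- data.frame(subject_id = "s1", frequency_hz = 2500,
                  noise_spectrum_db = c(6, 16, 26),
                  threshold_db = c(32, 42, 52))
  expect_equal(crNoiseSlope(d)$slope, 1)
  d$threshold_db <- c(40, 40, 40)
  expect_equal(crNoiseSlope(d)$slope, 0)
  dShort <- d[1, ]
  out <- crNoiseSlope(dShort)
  expect_true(is.na(out$slope))
  expect_true(out$flag_insufficient)
})

test_that("simulated experiments produce near-unit masking slopes", {
  prof <- list(makeProfile(quiet = 15, cr = 26, subjectSd = 2,
                           frequencies = 2500))
  ae <- simulateExperiment(prof, 3, frequencies = 2500,
                           noiseConditions = defaultNoiseConditions()[2:4],
                           epochNoiseRms = 1, seed = 44)
  sl <- crNoiseSlope(thresholdTable(conditionMetrics(ae)))
  expect_equal(median(sl$slope, na.rm = TRUE), 1, tolerance = 0.1)
})
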