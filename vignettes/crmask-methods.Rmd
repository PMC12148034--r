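---
title: "Methods: masked thresholds, critical ratios and the roex masking model"
author: "crmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked thresholds, critical ratios and the roex masking model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmask)
```

# Scope

`crmask` implements the analysis chain of an auditory-evoked-potential
(AEP) hearing-in-noise experiment: gated tone pips and band-limited
maskers, auditory brainstem response (ABR) peak metrics, masked
thresholds by the midpoint rule, critical ratios (CRs), roex
power-spectrum-model predictions, and repeated-measures group
statistics. Because raw laboratory recordings of this kind are rarely
deposited, the package ships a first-class synthetic experiment
generator whose output has the statistical structure the analysis
assumes; every estimator is validated against that generator's ground
truth.

# Stimuli and level arithmetic

**Tone pips.** `tonePip()` synthesises a short pure tone (default 5 ms
at 1, 2, 2.5, 3.15 or 4 kHz, 51.1/s presentation) whose onset and
offset are shaped by the rising and falling halves of a 4-term
Blackman–Harris window. Two choices were open here:

* *Gate family term count.* "Blackman–Harris" names a family; the
  4-term window is the common default in signal-processing practice
  and is what we implement. The window is evaluated on `2g + 1` points
  (g = gate samples) so its centre sample is exactly 1 and the gate
  hands over to the unit plateau without a seam.
* *Gates inside or outside the duration.* We count the 1-ms rise and
  fall inside the 5-ms total (so a 2.5 kHz pip at 48 kHz is 240
  samples with a unit envelope on samples 49–192). The alternative
  (5 ms plateau + 2 ms gates) is representable by passing a longer
  `duration`.

Pips alternate starting phase between 0 and π; averaging a phase pair
cancels any stimulus-following (cochlear-microphonic) component while
leaving the neural response intact. The generator can add such a
component (`cmAmplitude`) to exercise this cancellation.

**Maskers.** `bandNoise()` builds flat-spectrum noise in the frequency
domain: every FFT bin inside the passband (default 0–6.3 kHz) receives
equal magnitude and an independent uniform phase, bins outside are
zero, and the waveform RMS is calibrated to the condition's overall
level re 20 µPa. This makes the per-1/3-octave flatness exact by
construction and the stopband numerically empty. Synthesis starts at
the first positive bin: DC carries no acoustic meaning.

**Levels.** For flat noise of bandwidth Δf, overall level and spectrum
level are tied by `N0 = L − 10·log10(Δf)`; `spectrumLevel()` /
`overallLevel()` are exact inverses. The standard noise conditions are
44/54/64 dB overall on a 0–6.3 kHz band, i.e. spectrum levels of about
6/16/26 dB Hz⁻¹. Overall masker levels of this kind are often quoted
A-weighted; for flat noise limited to 0–6.3 kHz the A-weighted and
unweighted figures are close enough that the printed mapping to
spectrum levels follows the unweighted arithmetic, which is what the
package implements — `NoiseCondition` treats its `overallLevel` as dB
SPL over the flat band and enforces consistency with the spectrum
level to 0.5 dB.

# The synthetic ABR experiment

`simulateExperiment()` emulates, per subject × frequency × noise ×
level cell, the two replicate averaged traces an AEP rig produces
(each nominally the mean of 400 single-epoch sweeps in alternating
phase). Its deterministic response model is intentionally minimal —
just rich enough to carry the features the estimators consume:

* **Morphology.** The early ABR is modelled as a positive Gaussian
  pulse (P1) followed by a negative one (N1) one interpeak interval
  later (default 1 ms). The pulse width default of 0.17 ms SD
  (≈0.4 ms FWHM) gives single-peaked extrema well separated at ABR
  sampling rates.
* **Amplitude growth.** Peak-to-peak amplitude saturates with
  sensation level SL as `Amax·(1 − exp(−SL/τA))`, `Amax = 2 µV`,
  `τA = 10 dB` — typical songbird ABR magnitudes and a growth scale
  that makes responses clearly visible ~5–10 dB above threshold.
* **Latency.** P1 latency decays as
  `Lmin + Lspan·exp(−SL/τL)` (defaults 1.5 + 2·exp(−SL/20) ms) and is
  offset by the acoustic travel time from a speaker 0.5 m above the
  head (0.5/343 s ≈ 1.458 ms); latencies reported downstream are
  measured from this sound-at-ear onset.
* **Thresholds.** Each subject draws one quiet-threshold offset
  ~ Normal(0, `subjectSd`, default 3 dB). In noise, the effective
  threshold combines the quiet threshold with the masked component
  `N0 + CR` by **power summation**,
  `10·log10(10^(Tq/10) + 10^((N0+CR)/10))` — smooth, standard in
  masking models, and reducing to the correct quiet and
  masked-dominated limits (we prefer it to `max()`, which has a kink
  at the crossover). dB-for-dB masking growth, and hence CR
  noise-invariance, follows automatically wherever the masked term
  dominates. (Exactly at 10 dB dominance the power-sum slope is
  10/11 ≈ 0.91; it is within 0.05 of 1 from ~13 dB dominance.)
* **Residual EEG.** Additive white Gaussian noise with RMS
  `epochNoiseRms/√nEpochs`; the default single-epoch RMS of 2 µV puts
  the 400-epoch averaged-trace floor at 0.1 µV.
* **Level grids.** Real experiments step 5 dB near the expected
  threshold and 10–20 dB farther away, with a 60 dB SPL ceiling for
  suprathreshold comparisons. The default grid reproduces this: 5-dB
  steps within ±10 dB of the species-median expected threshold,
  10-dB steps up to 60.

The species profiles shipped by `defaultSpeciesProfiles()` encode the
qualitative comparative structure the pipeline is designed to resolve
— the nuthatch with the best quiet sensitivity but the highest CRs,
the titmouse with the lowest CRs, the chickadee intermediate, CR
differences confined to ≥ 2.5 kHz — with round-number thresholds and
CRs in the range typical of songbird AEP work (CRs ~24–32 dB). They
are configuration, not measurements.

**What the generator does not emulate:** real EEG's coloured spectrum
and artefacts (myogenic bursts, line noise), amplitude/latency
variability beyond the threshold offset, adaptation, anesthesia-depth
drift, and any cochlear nonlinearity. Passing tests therefore show
that the estimators are correct and well-calibrated *under the stated
statistical structure*, not that they are robust to every property of
real recordings; the prominence criterion below is the main knob a
user would revisit for real data.

# Peak detection and its central decision

A human observer calls a response "present" when a clear positive and
negative peak is visible. `detectPeaks()` automates this judgement:
after baseline correction (subtracting the pre-onset mean, which makes
all measures invariant to a constant voltage offset), P1 is the
*first* local maximum inside the search window (default 0–10 ms after
sound-at-ear; brainstem responses are early) whose voltage exceeds
**3× the baseline RMS**, and N1 the first subsequent local minimum
below the negative criterion. The 3× visibility proxy is the module's
central emulation decision, exposed as `promFactor`; the baseline RMS
is estimated from the pre-onset segment or supplied. Local extrema on
plateaus are credited to their earliest sample ("first peak"
semantics), and the implementation is verified sample-for-sample
against an independent brute-force scan on 1000 random traces. No
smoothing is applied by default (acquisition-side band-pass filtering
is assumed done); an optional moving average is available.

Two consequences are worth knowing. First, with white residual noise a
3σ criterion admits a few percent false "pairs" on pure noise; the
two-replicate rule below squares that rate per condition. Second,
because a response must *clear* the criterion, detection thresholds
sit ~3–4 dB above the true threshold under the default amplitude
growth — partly offset by the midpoint rule's −2.5 dB, leaving the
estimator with a small positive bias well inside the half-grid-step
tolerance used in validation.

# Thresholds, censoring and critical ratios

A level is *present* only when **both** replicates show a qualifying
pair (`classifyResponse()`); a single-replicate hit does not count.
`estimateThreshold()` then walks the level series down from the top:
the anchor is the lowest level of the unbroken present-run reaching
the maximum tested level, and the threshold is the midpoint between it
and the next quietest tested level — 2.5 dB below the anchor on a
5-dB grid, and implemented for arbitrary steps. The contiguous-run
rule is our resolution of an underdetermined case: observers track the
response down from clearly suprathreshold levels, so an isolated
detection below a miss (noise can cause both) neither rescues nor
moves the run. Series with no detection are censored `above_max`;
series whose run reaches the lowest tested level are censored
`below_min`; censored cells carry `NA` thresholds, are flagged, and
are excluded from CR computation (no imputation).

`computeCriticalRatio()` subtracts the masker spectrum level from an
uncensored masked threshold. The quiet condition has no spectrum
level, so no CR is defined there — quiet cells yield thresholds only.

# The roex power-spectrum model

Predictions use the standard symmetric rounded-exponential filter:
power weighting `W(g) = (1 + pg)·e^(−pg)` with `g = |f − f0|/f0`, and
`ERB = 4·f0/p` (these closed forms come from the auditory-filter
literature behind the ERB/K vocabulary, not from any one dataset).
`predictedThreshold()` evaluates `Ps = K·∫N(f)·W(f)df` by quadrature —
split at the cusp f0, skirts truncated where `W < 1e-6` for
integrability and speed — and reduces, for flat noise covering the
filter, to `N0 + 10·log10(ERB) + K` (verified to 0.1 dB over a grid of
f0 ∈ 1–4 kHz, p ∈ 8–40, K ∈ 0–10 dB). K is stored in dB and applied
as a linear power ratio inside the integral. `predictedCr()` is
`10·log10(ERB) + K`, the equal-power Fletcher relation when K = 0, and
is independent of noise level by construction. Filter parameters
(ERB or p, and K, per species × frequency) are user-supplied
configuration — published notched-noise estimates belong in a CSV the
user provides, not hard-coded in a package. Asymmetric filters are
supported via `p_lower`/`p_upper`-style custom spectra only insofar as
the user supplies them; the symmetric default reflects common
practice. `comparePredictions()` ranks species within frequency by
Kendall concordance under the efficiency-aware prediction and under a
bandwidth-only prediction with K forced equal, which is how the
bandwidth-vs-efficiency question is posed quantitatively.

# Group statistics

`fitMixedModel()` fits, on the (optionally log-transformed) response,
a linear mixed model with categorical fixed effects — species,
frequency, noise class (quiet/6/16/26 treated as a factor, with
`crNoiseSlope()` as the continuous complement) and their interactions
— and a per-subject random intercept, using `lmerTest` with
**Satterthwaite** denominator df. Production analyses of this design
historically used an AR(1) repeated-measures covariance with
Kenward–Roger df in SAS; the random-intercept/Satterthwaite
combination is the implementable desk-scale counterpart that preserves
the scientific content (fixed-effect structure, transform, contrasts),
and the fit report labels its df method so the two are never
conflated. Singular fits are flagged, not hidden. `reduceModel()`
drops interactions non-significant at α = 0.05 (respecting marginality)
and compares ML AICs of full vs reduced models. Log transforms are
the conventional normalising choice for CRs and ABR amplitudes, which
are right-skewed. `pairwiseContrasts()` reports all pairwise
differences of estimated marginal means with raw and Bonferroni
(`min(1, m·p)`) p-values.

**Calibration.** Monte-Carlo calibration (type-I error of the species
test, power for a built-in 8 dB species CR offset at 7/6/4 subjects)
needs hundreds of replicate experiments, so it runs on
`simulateCrTable()`, a table-level generator drawing per-subject CRs
directly: profile value + Normal(0, subjectSd) subject intercept +
Normal(0, residualSd) cell residual. The residual default of 1.5 dB is
the SD of the quantisation error a 5-dB estimation grid imposes
(5/√12 ≈ 1.44). This generator shares the mixed model's assumed
structure by design — it calibrates the inference machinery, not the
waveform pipeline, which is validated separately end-to-end.

# Problem sizes and numerical choices

The validation suite uses: the full study-scale simulation (3 species,
7/6/4 subjects, 5 frequencies, 4 noise conditions, ~6–8 levels, 2
replicates ≈ 4700 traces) for threshold recovery and CR
noise-invariance; 500 null and 100 offset replicates for statistical
calibration; 1000 random traces for the peak-scan oracle; and 24 kHz /
12 ms traces (288 samples) throughout — sizes chosen so the whole
suite runs in a few minutes on one core while keeping every check at
meaningful precision. Other constants: stimulus synthesis at 48 kHz
(covers the 6.3 kHz band with margin); quadrature relative tolerance
1e-9; filter-skirt truncation at 1e-6; detection search window 0–10 ms
post-onset.

# Known limitations

* The detection criterion is a proxy for trained-observer judgement;
  its false-positive/miss trade-off on real, coloured EEG noise will
  differ from the white-noise calibration here.
* Threshold estimates inherit the grid: accuracy is bounded by half
  the local step plus the detection bias, and censoring at the 60 dB
  ceiling occurs when masked thresholds approach it.
* The mixed model's df method is Satterthwaite on a random-intercept
  structure; denominator df from an AR(1)/Kenward–Roger analysis are
  not reproduced.
* Later ABR waves, frequency-following responses, raw-epoch artefact
  rejection, off-frequency listening and roex parameter *fitting*
  (notched-noise analysis) are out of scope.
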