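Package: crmask
Title: Critical Ratios and Masked Hearing Thresholds from Auditory
    Brainstem Responses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating masked hearing thresholds and critical
    ratios from auditory brainstem responses (ABRs). Provides gated
    tone-pip and band-limited masker synthesis with sound-level
    calibration arithmetic, a synthetic ABR-experiment generator with
    ground truth, P1/N1 peak extraction with amplitude and latency
    measurement, threshold estimation by the midpoint rule with
    censoring, critical-ratio computation, roex power-spectrum-model
    predictions of masked thresholds and critical ratios, and
    repeated-measures mixed-model summaries with Bonferroni-corrected
    pairwise contrasts. Trace sets are stored in a
    SummarizedExperiment-derived container with full condition metadata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, lme4, lmerTest, emmeans,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Electrophysiology, Software, Preprocessing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'crmask-package.R'
    'stimulus.R'
    'io.R'
    'synth.R'
    'metrics.R'
    'thresholds.R'
    'pipeline.R'
    'roex.R'
    'show-methods.R'
    'stats.R'
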