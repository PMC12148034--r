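#' @include pipeline.R
NULL

.noiseClassOf <- function(df) {
  if ("noise_class" %in% names(df)) return(as.character(df$noise_class))
  if ("noise_spectrum_db" %in% names(df))
    return(ifelse(is.na(df$noise_spectrum_db), "quiet",
                  as.character(df$noise_spectrum_db)))
  stop("no 'noise_class' or 'noise_spectrum_db' column")
}

#' Cell summaries (mean +/- s.e.m.)
#'
#' Grouped means and standard errors of one response per species x
#' frequency x noise class cell; single-observation cells get an NA
#' s.e.m. and are flagged.
#'
#' @param data data.frame with `species`, `frequency_hz`, a noise class
#'   (or `noise_spectrum_db`) column, and the response.
#' @param response name of the response column.
#' @return data.frame with `n`, `mean`, `sd`, `sem`, `flag_single`.
#' @export
summarizeCells <- function(data, response) {
  stopifnot(response %in% names(data))
  d <- data[!is.na(data[[response]]), ]
  d$noise_class <- .noiseClassOf(d)
  key <- interaction(d$species, d$frequency_hz, d$noise_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g) {
    y <- g[[response]]
    data.frame(species = g$species[1], frequency_hz = g$frequency_hz[1],
               noise_class = g$noise_class[1], response = response,
               n = length(y), mean = mean(y),
               sd = if (length(y) > 1) sd(y) else NA_real_,
               sem = if (length(y) > 1) sd(y) / sqrt(length(y)) else NA_real_,
               flag_single = length(y) == 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$species, out$frequency_hz, out$noise_class), ]
}

#' Fit a repeated-measures linear mixed model
#'
#' Linear mixed model with categorical fixed effects (any subset of
#' species, frequency and noise, with all their interactions by
#' default) and a per-subject random intercept, fitted with
#' \pkg{lmerTest}. The response may be log-transformed first (as is
#' usual for critical ratios and ABR amplitudes, which are
#' right-skewed). Per-term F tests use Satterthwaite denominator
#' degrees of freedom; the report labels the method. A singular fit is
#' flagged in the result, not silently dropped.
#'
#' @param data data.frame with `subject_id` plus the factor and
#'   response columns.
#' @param response response column name.
#' @param transform `"identity"` or `"log"` (natural log; requires a
#'   positive response).
#' @param fixed character subset of `c("species", "frequency", "noise")`.
#' @param interactions include all interactions among the fixed factors?
#' @return object of class `"crmaskMixedFit"`: list with `fit` (the
#'   `lmerModLmerTest`), `anova` (F table), `varcomp`, `singular`,
#'   `transform`, `dfMethod`, `formula`.
#' @seealso [pairwiseContrasts()], [reduceModel()].
#' @export
fitMixedModel <- function(data, response, transform = c("identity", "log"),
                          fixed = c("species", "frequency", "noise"),
                          interactions = TRUE) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(data), "subject_id" %in% names(data))
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  d$.y <- d[[response]]
  if (transform == "log") {
    if (any(d$.y <= 0)) stop("log transform requires a positive response")
    d$.y <- log(d$.y)
  }
  cols <- c(species = "species", frequency = "frequency_hz",
            noise = "noise")
  if ("noise" %in% fixed) d$noise <- .noiseClassOf(d)
  for (f in fixed) {
    cn <- cols[[f]]
    if (!cn %in% names(d)) stop("missing factor column: ", cn)
    d[[paste0(".", f)]] <- factor(d[[cn]])
    if (nlevels(d[[paste0(".", f)]]) < 2)
      stop("factor '", f, "' has fewer than two levels")
  }
  if ("species" %in% fixed) {
    nsub <- tapply(d$subject_id, d$.species,
                   function(x) length(unique(x)))
    if (any(nsub < 2)) stop("need >= 2 subjects per species")
  }
  terms <- paste0(".", fixed)
  fx <- paste(terms, collapse = if (interactions) " * " else " + ")
  fml <- as.formula(paste(".y ~", fx, "+ (1 | subject_id)"))
  fit <- lmerTest::lmer(fml, data = d,
                        contrasts = setNames(
                          rep(list("contr.sum"), length(terms)), terms))
  an <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  an$term <- sub("^\\.", "", gsub(":\\.", ":", rownames(an)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, anova = an, varcomp = vc,
                 singular = lme4::isSingular(fit), transform = transform,
                 dfMethod = "Satterthwaite", formula = fml, data = d),
            class = "crmaskMixedFit")
}

#' @export
print.crmaskMixedFit <- function(x, ...) {
  cat("Linear mixed model (subject random intercept), ",
      "df method: ", x$dfMethod, "\n", sep = "")
  cat("Response transform:", x$transform,
      if (x$singular) " [singular fit]" else "", "\n")
  print(x$anova[, c("term", "NumDF", "DenDF", "F value", "Pr(>F)")],
        row.names = FALSE)
  invisible(x)
}

#' Drop non-significant interactions and compare AIC
#'
#' Model-reduction helper: removes interaction terms whose F test is
#' non-significant at `alpha` (highest order first), refits, and
#' compares the AIC of the full and reduced models under maximum
#' likelihood.
#'
#' @param fit a `"crmaskMixedFit"` from [fitMixedModel()].
#' @param alpha significance threshold for keeping an interaction.
#' @return list with `full`, `reduced` (both `crmaskMixedFit`-like),
#'   `aic` (named numeric), `dropped` (character).
#' @export
reduceModel <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "crmaskMixedFit"))
  an <- fit$anova
  inter <- an$term[grepl(":", an$term)]
  drop <- an$term[grepl(":", an$term) & an[["Pr(>F)"]] > alpha]
  ## keep lower-order interactions that sit inside a retained higher one
  keepHigh <- setdiff(inter, drop)
  drop <- drop[!vapply(drop, function(tm) {
    parts <- strsplit(tm, ":")[[1]]
    any(vapply(keepHigh, function(h)
      all(parts %in% strsplit(h, ":")[[1]]) && h != tm, logical(1)))
  }, logical(1))]
  if (!length(drop))
    return(list(full = fit, reduced = fit,
                aic = c(full = AIC(fit$fit), reduced = AIC(fit$fit)),
                dropped = character()))
  d <- fit$data
  rhs <- attr(stats::terms(fit$fit), "term.labels")
  rhs <- rhs[!grepl("subject_id", rhs)]
  rhs <- setdiff(rhs, gsub("(^|:)", "\\1.", drop))
  fml <- as.formula(paste(".y ~", paste(rhs, collapse = " + "),
                          "+ (1 | subject_id)"))
  red <- lmerTest::lmer(fml, data = d)
  fullML <- stats::update(fit$fit, REML = FALSE)
  redML <- stats::update(red, REML = FALSE)
  anR <- as.data.frame(stats::anova(red, type = 3, ddf = "Satterthwaite"))
  anR$term <- sub("^\\.", "", gsub(":\\.", ":", rownames(anR)))
  reduced <- structure(list(fit = red, anova = anR,
                            varcomp = as.data.frame(lme4::VarCorr(red)),
                            singular = lme4::isSingular(red),
                            transform = fit$transform,
                            dfMethod = fit$dfMethod, formula = fml,
                            data = d), class = "crmaskMixedFit")
  list(full = fit, reduced = reduced,
       aic = c(full = AIC(fullML), reduced = AIC(redML)),
       dropped = gsub("\\.", "", drop))
}

#' Bonferroni-corrected pairwise contrasts
#'
#' All pairwise differences of estimated marginal means of one factor
#' (optionally within levels of another), with raw and Bonferroni-
#' adjusted p-values (adjusted = min(1, m x p)).
#'
#' @param fit a `"crmaskMixedFit"` from [fitMixedModel()].
#' @param factor one of `"species"`, `"frequency"`, `"noise"`.
#' @param within optional conditioning factor.
#' @return data.frame of contrasts with `estimate`, `se`, `df`,
#'   `t_ratio`, `p_raw`, `p_bonferroni`.
#' @export
pairwiseContrasts <- function(fit, factor, within = NULL) {
  stopifnot(inherits(fit, "crmaskMixedFit"))
  spec <- paste0(".", factor)
  by <- if (is.null(within)) NULL else paste0(".", within)
  emm <- emmeans::emmeans(fit$fit, specs = spec, by = by,
                          lmer.df = "satterthwaite")
  raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  adj <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                         adjust = "bonferroni"))
  out <- raw
  names(out)[names(out) == "SE"] <- "se"
  names(out)[names(out) == "t.ratio"] <- "t_ratio"
  names(out)[names(out) == "p.value"] <- "p_raw"
  out$p_bonferroni <- adj$p.value
  if (!is.null(by)) names(out)[names(out) == by] <- within
  out
}

#' Per-cell slope of threshold against noise spectrum level
#'
#' Least-squares slope of masked threshold (dB SPL) on masker spectrum
#' level (dB Hz^-1) per subject x frequency. A slope of 1 means
#' thresholds rise dB-for-dB with the noise, i.e. critical ratios are
#' independent of noise level; a slope of 0 means masking is absent.
#' Cells with fewer than two uncensored masked thresholds return NA
#' with a flag.
#'
#' @param thresholds data.frame from [thresholdTable()] (or any table
#'   with `subject_id`, `frequency_hz`, `noise_spectrum_db`,
#'   `threshold_db` and optionally `censored`/`is_quiet`).
#' @return data.frame with `slope` and `n_levels` per cell.
#' @export
crNoiseSlope <- function(thresholds) {
  d <- thresholds
  if ("is_quiet" %in% names(d)) d <- d[!d$is_quiet, ]
  if ("censored" %in% names(d)) d <- d[d$censored == "none", ]
  d <- d[!is.na(d$threshold_db) & !is.na(d$noise_spectrum_db), ]
  key <- interaction(d$subject_id, d$frequency_hz, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g) {
    ok <- length(unique(g$noise_spectrum_db)) >= 2
    data.frame(subject_id = g$subject_id[1],
               frequency_hz = g$frequency_hz[1],
               species = if ("species" %in% names(g)) g$species[1] else NA,
               n_levels = nrow(g),
               slope = if (ok)
                 unname(coef(lm(threshold_db ~ noise_spectrum_db,
                                data = g))[2]) else NA_real_,
               flag_insufficient = !ok, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
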