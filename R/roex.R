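#' @include AllGenerics.R
NULL

#' Roex filter power weighting
#'
#' Symmetric rounded-exponential weighting
#' \eqn{W(g) = (1 + pg)e^{-pg}} with normalized frequency offset
#' \eqn{g = |f - f_0| / f_0}; equals 1 at the center frequency and
#' decreases monotonically away from it.
#'
#' @param filter a [RoexFilter-class].
#' @param frequency Hz (vectorized); must be > 0.
#' @return power weight(s) in [0, 1].
#' @examples
#' fl <- RoexFilter(2000, p = 16)
#' roexWeight(fl, 2000)                   # 1
#' roexWeight(fl, 2000 * (1 + 1 / 16))    # 2/e
#' @export
roexWeight <- function(filter, frequency) {
  stopifnot(is(filter, "RoexFilter"), all(frequency > 0))
  g <- abs(frequency - filter@centerFrequency) / filter@centerFrequency
  (1 + filter@p * g) * exp(-filter@p * g)
}

#' @rdname erbOf
#' @export
setMethod("erbOf", "RoexFilter", function(filter) filter@erb)

## Half-width of the filter support (in g units) beyond which the
## weight is below `floor`; used to truncate quadrature.
.roexSupport <- function(p, floor = 1e-6) {
  f <- function(g) (1 + p * g) * exp(-p * g) - floor
  uniroot(f, c(0, 1000 / p), tol = 1e-10)$root
}

#' Flat and notched noise spectrum densities
#'
#' Helpers returning `function(f)` giving linear intensity density
#' (re (20 uPa)^2 per Hz) for use with [predictedThreshold()]:
#' `flatSpectrumDensity` is constant at spectrum level `n0Db` inside
#' `[lowCut, highCut]` and zero outside; `notchedSpectrumDensity`
#' additionally zeroes `[notchLow, notchHigh]`.
#'
#' @param n0Db spectrum level, dB Hz^-1.
#' @param lowCut,highCut,notchLow,notchHigh band/notch edges, Hz.
#' @return a function of frequency (Hz).
#' @export
flatSpectrumDensity <- function(n0Db, lowCut = 0, highCut = Inf) {
  force(n0Db); force(lowCut); force(highCut)
  function(f) ifelse(f >= lowCut & f <= highCut, 10^(n0Db / 10), 0)
}

#' @rdname flatSpectrumDensity
#' @export
notchedSpectrumDensity <- function(n0Db, notchLow, notchHigh,
                                   lowCut = 0, highCut = Inf) {
  flat <- flatSpectrumDensity(n0Db, lowCut, highCut)
  function(f) ifelse(f > notchLow & f < notchHigh, 0, flat(f))
}

#' Masked threshold predicted by the power-spectrum model
#'
#' Under the power-spectrum model of masking, a tone at the filter's
#' center frequency is detected when its power reaches K times the
#' noise power passed by the filter:
#' \deqn{P_s = K \int N(f)\,W(f)\,df,}
#' returned as \eqn{10\log_{10} P_s} in dB SPL. For a flat spectrum
#' level \eqn{N_0} covering the filter this reduces to
#' \eqn{N_0 + 10\log_{10}(ERB) + K}. The integral is evaluated by
#' quadrature over the filter support (truncated where the weight falls
#' below `weightFloor`), so arbitrary (e.g. notched) spectra are
#' supported.
#'
#' @param filter a [RoexFilter-class].
#' @param noiseSpectrum a [NoiseCondition-class] (flat over its band) or
#'   a `function(f)` returning linear intensity density per Hz.
#' @param weightFloor truncation level for the filter skirts.
#' @return threshold in dB SPL.
#' @examples
#' fl <- RoexFilter(2000, erb = 500, kDb = 3)
#' predictedThreshold(fl, NoiseCondition(spectrumLevel = 26))
#' 26 + 10 * log10(500) + 3   # closed form
#' @export
predictedThreshold <- function(filter, noiseSpectrum, weightFloor = 1e-6) {
  stopifnot(is(filter, "RoexFilter"))
  if (is(noiseSpectrum, "NoiseCondition")) {
    if (isQuiet(noiseSpectrum))
      stop("quiet condition: no masked threshold to predict")
    noiseSpectrum <- flatSpectrumDensity(spectrumLevel(noiseSpectrum),
                                         noiseSpectrum@lowCut,
                                         noiseSpectrum@highCut)
  }
  f0 <- filter@centerFrequency
  gMax <- .roexSupport(filter@p, weightFloor)
  lower <- max(0, f0 * (1 - gMax))
  upper <- f0 * (1 + gMax)
  integrand <- function(f) noiseSpectrum(f) * roexWeight(filter, pmax(f, 1e-9))
  ## split at f0 so the quadrature sees the cusp as an endpoint
  int <- integrate(integrand, lower, f0, rel.tol = 1e-9,
                   subdivisions = 1000L)$value +
    integrate(integrand, f0, upper, rel.tol = 1e-9,
              subdivisions = 1000L)$value
  if (int <= 0)
    stop("quiet condition: the noise spectrum is zero over the filter support")
  10 * log10(10^(filter@kDb / 10) * int)
}

#' Critical ratio predicted from filter bandwidth and efficiency
#'
#' For a flat broadband masker the predicted critical ratio is
#' \eqn{10\log_{10}(ERB) + K}; with \eqn{K = 0} dB this is the classic
#' equal-power relation between critical ratio and filter bandwidth.
#' The prediction is independent of the masker spectrum level.
#'
#' @param filter a [RoexFilter-class].
#' @return predicted critical ratio, dB.
#' @examples
#' predictedCr(RoexFilter(2000, erb = 100))        # 20 dB, equal power
#' predictedCr(RoexFilter(2000, erb = 500, kDb = 3))
#' @export
predictedCr <- function(filter) {
  stopifnot(is(filter, "RoexFilter"))
  10 * log10(filter@erb) + filter@kDb
}

#' Compare predicted and observed critical ratios across species
#'
#' Merges a filter-parameter table with observed critical ratios and
#' evaluates, per frequency, how well the species ordering of the
#' observations matches two predictions: the efficiency-aware roex
#' prediction \eqn{10\log_{10}(ERB) + K}, and the bandwidth-only
#' prediction with K forced equal across species
#' (\eqn{10\log_{10}(ERB)}). Agreement is measured by the Kendall rank
#' correlation across species.
#'
#' @param filters data.frame with columns `species`, `frequency_hz`,
#'   `k_db`, and `erb_hz` or `p` (filter parameters are user-supplied
#'   configuration, e.g. from published notched-noise estimates).
#' @param observed data.frame with columns `species`, `frequency_hz`,
#'   `cr_db` (replicate rows are averaged per cell).
#' @return list with `cells` (per species x frequency: predicted,
#'   bandwidth-only predicted, observed mean, difference) and
#'   `concordance` (per frequency: Kendall tau for both prediction
#'   modes; NA with a flag when fewer than two species are present).
#' @export
comparePredictions <- function(filters, observed) {
  stopifnot(all(c("species", "frequency_hz", "k_db") %in% names(filters)),
            all(c("species", "frequency_hz", "cr_db") %in% names(observed)))
  if (!"erb_hz" %in% names(filters)) {
    if (!"p" %in% names(filters))
      stop("'filters' needs an 'erb_hz' or 'p' column")
    filters$erb_hz <- 4 * filters$frequency_hz / filters$p
  }
  obs <- aggregate(cr_db ~ species + frequency_hz, data = observed,
                   FUN = mean)
  names(obs)[names(obs) == "cr_db"] <- "observed_cr_db"
  cells <- merge(filters, obs, by = c("species", "frequency_hz"))
  if (nrow(cells) < nrow(obs))
    stop("alignment error: observed cells without matching filter parameters")
  cells$predicted_cr_db <- 10 * log10(cells$erb_hz) + cells$k_db
  cells$predicted_bw_only_db <- 10 * log10(cells$erb_hz)
  cells$difference_db <- cells$observed_cr_db - cells$predicted_cr_db
  conc <- do.call(rbind, lapply(split(cells, cells$frequency_hz),
    function(d) {
      nsp <- length(unique(d$species))
      data.frame(frequency_hz = d$frequency_hz[1], n_species = nsp,
        tau_efficiency = if (nsp >= 2)
          stats::cor(d$predicted_cr_db, d$observed_cr_db,
                     method = "kendall") else NA_real_,
        tau_bandwidth_only = if (nsp >= 2)
          stats::cor(d$predicted_bw_only_db, d$observed_cr_db,
                     method = "kendall") else NA_real_,
        degenerate = nsp < 2)
    }))
  rownames(conc) <- NULL
  list(cells = cells[order(cells$frequency_hz, cells$species), ],
       concordance = conc)
}
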