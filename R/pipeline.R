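#' @include thresholds.R
NULL

## Fast peak scan for matrix columns; mirrors detectPeaks() without
## per-trace S4 construction.
.peaksRow <- function(x, times, onset, searchWindow, promFactor,
                      baselineRms = NULL) {
  pre <- x[times < onset]
  if (length(pre) >= 5) x <- x - mean(pre)     # baseline correction
  if (is.null(baselineRms))
    baselineRms <- sqrt(mean((pre - mean(pre))^2))
  hit <- .scanPeaks(x, times, onset + searchWindow[1],
                    onset + searchWindow[2], promFactor * baselineRms)
  if (is.null(hit))
    return(c(found = 0, p1_time = NA, p1_uv = NA, n1_time = NA,
             n1_uv = NA, amplitude_uv = NA, latency_p1_ms = NA,
             latency_n1_ms = NA))
  p1 <- hit["p1"]; n1 <- hit["n1"]
  c(found = 1, p1_time = times[p1], p1_uv = x[p1], n1_time = times[n1],
    n1_uv = x[n1], amplitude_uv = x[p1] - x[n1],
    latency_p1_ms = times[p1] - onset, latency_n1_ms = times[n1] - onset)
}

#' Per-trace peak table
#'
#' Runs the P1/N1 scan of [detectPeaks()] on every trace of an
#' experiment and returns one row per trace (replicate level).
#'
#' @param x an [AbrExperiment-class].
#' @param searchWindow,promFactor,baselineRms as in [detectPeaks()].
#' @return data.frame: condition metadata plus `found`, peak times and
#'   voltages, `amplitude_uv`, `latency_p1_ms`, `latency_n1_ms`.
#' @export
tracePeaks <- function(x, searchWindow = c(0, 10), promFactor = 3,
                       baselineRms = NULL) {
  stopifnot(is(x, "AbrExperiment"))
  m <- S4Vectors::metadata(x)
  times <- traceTimes(x)
  a <- SummarizedExperiment::assay(x, "voltage")
  res <- t(vapply(seq_len(ncol(a)), function(i)
    .peaksRow(a[, i], times, m$onset, searchWindow, promFactor,
              baselineRms), numeric(8)))
  out <- cbind(as.data.frame(SummarizedExperiment::colData(x)),
               as.data.frame(res))
  out$found <- out$found > 0
  rownames(out) <- NULL
  out
}

#' Per-condition response metrics
#'
#' Collapses the two replicates of every subject x frequency x noise x
#' level cell: the response is `present` only when both replicates
#' showed a qualifying P1/N1 pair, and amplitude/latencies are measured
#' on the replicate-averaged trace (the average of the two 400-epoch
#' means).
#'
#' @inheritParams tracePeaks
#' @return data.frame keyed by subject, species, frequency, noise class
#'   and level, with `present`, `amplitude_uv`, `latency_p1_ms`,
#'   `latency_n1_ms` (NA when not measurable).
#' @export
conditionMetrics <- function(x, searchWindow = c(0, 10), promFactor = 3,
                             baselineRms = NULL) {
  stopifnot(is(x, "AbrExperiment"))
  m <- S4Vectors::metadata(x)
  times <- traceTimes(x)
  a <- SummarizedExperiment::assay(x, "voltage")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  key <- interaction(cd$subject_id, cd$frequency_hz, cd$noise_class,
                     cd$level_db, drop = TRUE)
  groups <- split(seq_len(nrow(cd)), key)
  rows <- lapply(groups, function(idx) {
    if (length(idx) != 2)
      stop("each condition must have exactly two replicate traces")
    p1 <- .peaksRow(a[, idx[1]], times, m$onset, searchWindow,
                    promFactor, baselineRms)
    p2 <- .peaksRow(a[, idx[2]], times, m$onset, searchWindow,
                    promFactor, baselineRms)
    avg <- .peaksRow((a[, idx[1]] + a[, idx[2]]) / 2, times, m$onset,
                     searchWindow, promFactor,
                     if (is.null(baselineRms)) NULL else
                       baselineRms / sqrt(2))
    present <- p1["found"] > 0 && p2["found"] > 0
    meas <- if (present && avg["found"] > 0) avg else
      c(found = 0, p1_time = NA, p1_uv = NA, n1_time = NA, n1_uv = NA,
        amplitude_uv = NA, latency_p1_ms = NA, latency_n1_ms = NA)
    cbind(cd[idx[1], c("subject_id", "species", "frequency_hz",
                       "level_db", "noise_overall_db",
                       "noise_spectrum_db", "is_quiet", "noise_class")],
          data.frame(present = present,
                     amplitude_uv = unname(meas["amplitude_uv"]),
                     latency_p1_ms = unname(meas["latency_p1_ms"]),
                     latency_n1_ms = unname(meas["latency_n1_ms"])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$frequency_hz, out$noise_class,
            -out$level_db), ]
}

#' Threshold table from per-condition metrics
#'
#' Applies [estimateThreshold()] within every subject x frequency x
#' noise cell of a [conditionMetrics()] table.
#'
#' @param metrics data.frame from [conditionMetrics()].
#' @return data.frame with `threshold_db`, `censored`,
#'   `lowest_detected_db`, `next_quietest_db` per cell.
#' @export
thresholdTable <- function(metrics) {
  need <- c("subject_id", "species", "frequency_hz", "noise_class",
            "level_db", "present")
  stopifnot(all(need %in% names(metrics)))
  key <- interaction(metrics$subject_id, metrics$frequency_hz,
                     metrics$noise_class, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(metrics)), key), function(idx) {
    d <- metrics[idx, ]
    est <- estimateThreshold(d$level_db, d$present)
    data.frame(subject_id = d$subject_id[1], species = d$species[1],
               frequency_hz = d$frequency_hz[1],
               noise_class = d$noise_class[1],
               noise_spectrum_db = d$noise_spectrum_db[1],
               is_quiet = d$is_quiet[1],
               threshold_db = est@threshold, censored = est@censored,
               lowest_detected_db = est@lowestDetectedLevel,
               next_quietest_db = est@nextQuietestLevel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Critical-ratio table from thresholds
#'
#' One critical ratio (threshold minus spectrum level) per uncensored
#' masked-threshold cell; quiet and censored cells are dropped.
#'
#' @param thresholds data.frame from [thresholdTable()].
#' @return the masked subset with a `cr_db` column appended.
#' @export
criticalRatioTable <- function(thresholds) {
  need <- c("is_quiet", "censored", "threshold_db", "noise_spectrum_db")
  stopifnot(all(need %in% names(thresholds)))
  keep <- !thresholds$is_quiet & thresholds$censored == "none"
  out <- thresholds[keep, ]
  out$cr_db <- out$threshold_db - out$noise_spectrum_db
  rownames(out) <- NULL
  out
}
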