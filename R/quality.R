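#' Detect flat (null-data) regions
#'
#' Flags maximal runs where the sample-to-sample change stays within `tol`
#' for at least `min_len` seconds, plus any missing samples. Runs sitting
#' at the series' global extremes are left to [detect_saturation()], so the
#' two screens report disjoint regions.
#'
#' @param series numeric vector.
#' @param min_len minimum run duration in seconds.
#' @param tol absolute tolerance in signal units (0 = exact repetition,
#'   matching the null-data reading).
#' @param fs sampling rate in Hz.
#' @return Tibble of regions: `start_idx`, `end_idx` (1-based, inclusive),
#'   `type` (`"flat"` or `"null"`).
#' @export
detect_flat <- function(series, min_len = 0.2, tol = 0, fs = 125) {
  stopifnot(length(series) > 0)
  out <- list()
  nas <- rle(is.na(series))
  if (any(nas$values)) {
    ends <- cumsum(nas$lengths)
    starts <- ends - nas$lengths + 1L
    for (i in which(nas$values)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start_idx = starts[i], end_idx = ends[i], type = "null")
    }
  }
  x <- series
  x[is.na(x)] <- Inf                       # NA runs reported separately
  min_samples <- max(2L, ceiling(min_len * fs))
  r <- rle(abs(diff(x)) <= tol)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gmax <- max(series, na.rm = TRUE)
  gmin <- min(series, na.rm = TRUE)
  for (i in which(r$values & r$lengths >= min_samples - 1L)) {
    level <- x[starts[i]]
    if (is.finite(level) && (abs(level - gmax) <= tol || abs(level - gmin) <= tol)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      start_idx = starts[i], end_idx = ends[i] + 1L, type = "flat")
  }
  if (!length(out)) {
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          type = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_idx)
}

#' Detect saturated (clipped) regions
#'
#' Flags plateaus at the series' global maximum or minimum -- the signature
#' of clipping in valleys and peaks.
#'
#' @param series numeric vector.
#' @param min_run minimum plateau length in samples.
#' @return Tibble of regions: `start_idx`, `end_idx`, `type`
#'   (`"saturation_high"` / `"saturation_low"`).
#' @export
detect_saturation <- function(series, min_run = 3L) {
  stopifnot(length(series) > 0)
  x <- series[!is.na(series)]
  if (!length(x)) {
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          type = character()))
  }
  out <- list()
  for (side in c("high", "low")) {
    lev <- if (side == "high") max(x) else min(x)
    r <- rle(!is.na(series) & series == lev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= min_run)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start_idx = starts[i], end_idx = ends[i],
        type = paste0("saturation_", side))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          type = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_idx)
}

#' Band-pass filter and MinMax-normalize a PPG segment
#'
#' Fourth-order Butterworth band-pass over `[0.5, 8]` Hz applied
#' forward-backward (zero phase, preserving landmark timing), then scaled
#' to exactly `[0, 1]` over the segment.
#'
#' @param segment numeric PPG segment.
#' @param fs sampling rate in Hz.
#' @param band cutoff frequencies in Hz.
#' @param order filter order.
#' @return The filtered, normalized segment.
#' @export
filter_ppg_sq <- function(segment, fs = 125, band = c(0.5, 8), order = 4) {
  if (diff(range(segment)) <= .Machine$double.eps) {
    stop("degenerate (constant) segment: MinMax normalization undefined")
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, segment)
  rng <- range(y)
  if (diff(rng) <= .Machine$double.eps) {
    stop("degenerate (constant) segment: MinMax normalization undefined")
  }
  (y - rng[1]) / diff(rng)
}

#' Moment coefficient of skewness
#'
#' Third central moment over the 1.5 power of the second central moment
#' (population moments).
#'
#' @param x numeric vector, length at least 3, non-constant.
#' @return Dimensionless skewness.
#' @export
moment_skewness <- function(x) {
  if (length(x) < 3L) stop("skewness needs at least 3 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps) stop("skewness undefined for zero variance")
  mean((x - m)^3) / m2^1.5
}

# Slope-sum-function onsets: accumulate positive slopes over a 128 ms
# window, find threshold crossings with a 0.3 s refractory period, then
# refine each onset to the waveform minimum in the preceding 150 ms.
ssf_onsets <- function(x, fs = 125) {
  w <- max(2L, round(0.128 * fs))
  s <- pmax(diff(x), 0)
  cs <- cumsum(s)
  ssf <- cs - c(rep(0, w), cs[seq_len(length(cs) - w)])
  peak <- stats::quantile(ssf, 0.95, names = FALSE)
  if (!is.finite(peak) || peak <= 1e-9) return(integer(0))
  thr <- 0.5 * peak
  above <- ssf >= thr
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  refractory <- round(0.3 * fs)
  back <- round(0.15 * fs)
  onsets <- integer(0)
  last <- -refractory
  for (cr in crossings) {
    if (cr - last < refractory) next
    lo <- max(1L, cr - back)
    win <- x[lo:cr]
    onset <- lo + which.min(win) - 1L
    if (!length(onsets) || onset - onsets[length(onsets)] >= refractory) {
      onsets <- c(onsets, onset)
      last <- cr
    }
  }
  onsets
}

#' Delineate onset-to-onset pulses
#'
#' Pulse onsets are located with a slope-sum-function detector with
#' adaptive thresholding; each pulse spans one onset to the next.
#'
#' @param segment numeric waveform segment (filtered PPG or ABP).
#' @param fs sampling rate in Hz.
#' @return Tibble with one row per complete pulse: `onset_idx` (1-based
#'   index into the segment), `duration` (s), `dbp` (min), `sbp` (max),
#'   `skewness`, and a list-column `samples`. Zero rows signal marker
#'   failure.
#' @export
delineate_pulses <- function(segment, fs = 125) {
  onsets <- ssf_onsets(segment, fs)
  if (length(onsets) < 2L) {
    return(tibble::tibble(onset_idx = integer(), duration = numeric(),
                          dbp = numeric(), sbp = numeric(),
                          skewness = numeric(), samples = list()))
  }
  purrr::map_dfr(seq_len(length(onsets) - 1L), function(i) {
    idx <- onsets[i]:(onsets[i + 1L] - 1L)
    p <- segment[idx]
    tibble::tibble(
      onset_idx = onsets[i], duration = length(p) / fs,
      dbp = min(p), sbp = max(p),
      skewness = tryCatch(moment_skewness(p), error = function(e) NA_real_),
      samples = list(p)
    )
  })
}

#' Per-segment pulse acceptance (ABP signal quality)
#'
#' A segment's pulse set is accepted when every pulse duration lies in
#' `[0.5, 1.5]` s (inclusive), the pulse count lies in `[10, 30]`
#' (inclusive), every pulse pressure (SBP - DBP) exceeds 10 mmHg, and
#' every pulse skewness exceeds zero.
#'
#' @param pulses tibble from [delineate_pulses()].
#' @param duration_range,count_range,min_pulse_pressure,min_skewness
#'   overridable thresholds (defaults are the protocol values).
#' @return A `quality_verdict`: list with `accepted` and `failed_checks`
#'   (subset of `marker`, `pulse_count`, `pulse_duration`,
#'   `pulse_pressure`, `skewness`).
#' @export
abp_sq <- function(pulses, duration_range = c(0.5, 1.5),
                   count_range = c(10L, 30L), min_pulse_pressure = 10,
                   min_skewness = 0) {
  failed <- character(0)
  if (nrow(pulses) == 0L) {
    failed <- "marker"
  } else {
    if (nrow(pulses) < count_range[1] || nrow(pulses) > count_range[2])
      failed <- c(failed, "pulse_count")
    if (any(pulses$duration < duration_range[1] |
            pulses$duration > duration_range[2]))
      failed <- c(failed, "pulse_duration")
    if (any(pulses$sbp - pulses$dbp <= min_pulse_pressure))
      failed <- c(failed, "pulse_pressure")
    if (any(is.na(pulses$skewness)) || any(pulses$skewness <= min_skewness))
      failed <- c(failed, "skewness")
  }
  quality_verdict(failed)
}

quality_verdict <- function(failed_checks) {
  structure(list(accepted = length(failed_checks) == 0L,
                 failed_checks = failed_checks),
            class = "quality_verdict")
}

#' @export
print.quality_verdict <- function(x, ...) {
  if (x$accepted) cat("<quality_verdict> accepted\n")
  else cat("<quality_verdict> rejected:", paste(x$failed_checks, collapse = ", "), "\n")
  invisible(x)
}

#' Full quality chain for one 15-s segment
#'
#' Runs the flat and saturation screens on both channels, filters and
#' normalizes the PPG, delineates pulses on both channels, and applies the
#' pulse acceptance rules to the ABP pulses (and the duration/count rules
#' to the PPG pulses).
#'
#' @param abp,ppg the two channels of one segment.
#' @param fs sampling rate in Hz.
#' @param config quality configuration block (see [bp_config()]).
#' @return list with `verdict` (a `quality_verdict`), `abp_pulses`,
#'   `ppg_pulses`, and `ppg_filtered`.
#' @export
check_segment <- function(abp, ppg, fs = 125, config = bp_config()$quality) {
  failed <- character(0)
  for (ch in list(abp, ppg)) {
    if (nrow(detect_flat(ch, config$flat_min_len, config$flat_tol, fs))) {
      failed <- c(failed, "flat")
      break
    }
  }
  for (ch in list(abp, ppg)) {
    if (nrow(detect_saturation(ch, config$sat_min_run))) {
      failed <- c(failed, "peak")
      break
    }
  }
  ppg_f <- tryCatch(
    filter_ppg_sq(ppg, fs, config$ppg_band, config$filter_order),
    error = function(e) NULL)
  if (is.null(ppg_f)) {
    return(list(verdict = quality_verdict(unique(c(failed, "flat"))),
                abp_pulses = NULL, ppg_pulses = NULL, ppg_filtered = NULL))
  }
  ppg_pulses <- delineate_pulses(ppg_f, fs)
  if (nrow(ppg_pulses) < config$count_range[1] ||
      nrow(ppg_pulses) > config$count_range[2]) {
    failed <- c(failed, "pulse_count")
  }
  abp_pulses <- delineate_pulses(abp, fs)
  verdict <- abp_sq(abp_pulses,
                    duration_range = config$duration_range,
                    count_range = config$count_range,
                    min_pulse_pressure = config$min_pulse_pressure,
                    min_skewness = config$min_skewness)
  failed <- unique(c(failed, verdict$failed_checks))
  list(verdict = quality_verdict(failed), abp_pulses = abp_pulses,
       ppg_pulses = ppg_pulses, ppg_filtered = ppg_f)
}
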