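#' Synthetic subjects and paired ABP/PPG waveform records
#'
#' The generator renders arterial-pressure beats as smooth piecewise
#' half-cosine segments (systolic upstroke, fall to the dicrotic notch,
#' dicrotic bump, diastolic decay), so every landmark -- onset, systolic
#' peak, dicrotic notch -- sits at an exactly known sample with an exactly
#' known value. The PPG channel is derived from the ABP by a fixed,
#' documented transform (unit scaling, 80 ms delay, second-order 8 Hz
#' low-pass, mild power nonlinearity) plus optional additive noise, which
#' keeps the mapping learnable while exercising every downstream stage.
#'
#' @name synthgen
NULL

#' Draw a synthetic subject
#'
#' Ages are uniform over the 18-89 year analysis range; baseline diastolic
#' and systolic pressures are drawn around 64.5 +/- 9.5 and 131 +/- 20 mmHg
#' (the distribution of the intended ICU cohort) with the pulse pressure
#' kept above 15 mmHg; the mean heart period is kept well inside the
#' physiological 0.5-1.5 s pulse-duration band so that beat-to-beat jitter
#' cannot leave it.
#'
#' @param seed integer seed; the same seed always yields the same subject.
#' @return A one-row tibble: `subject_id`, `age`, `gender`, `baseline_dbp`,
#'   `baseline_sbp`, `mean_heart_period`.
#' @export
make_subject <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  age <- stats::runif(1, 18, 89)
  gender <- sample(c("female", "male"), 1L)
  dbp <- min(max(stats::rnorm(1, 64.5, 9.5), 45), 100)
  pp <- min(max(stats::rnorm(1, 66, 15), 20), 95)
  sbp <- min(dbp + pp, 172)
  mhp <- min(max(stats::rnorm(1, 0.85, 0.12), 0.58), 1.12)
  tibble::tibble(
    subject_id = sprintf("S%06d", as.integer(seed) %% 1000000L),
    age = age, gender = gender,
    baseline_dbp = dbp, baseline_sbp = sbp,
    mean_heart_period = mhp
  )
}

#' Construct a beat template
#'
#' Places the systolic peak and dicrotic notch at fixed sample indices
#' (1-based, onset at index 1) derived from the requested fractions of the
#' beat duration.
#'
#' @param duration beat duration in seconds, must lie in `[0.5, 1.5]`.
#' @param onset_value diastolic (onset) pressure in mmHg.
#' @param sbp systolic peak pressure in mmHg.
#' @param fs sampling rate in Hz.
#' @param sp_frac,dn_frac fractional positions of the systolic peak and
#'   dicrotic notch within the beat.
#' @param dn_level dicrotic-notch value as a fraction of pulse pressure
#'   above the onset value.
#' @param bump_frac dicrotic (reflected-wave) bump height as a fraction of
#'   pulse pressure.
#' @param end_offset pressure above `onset_value` at the last sample, mmHg;
#'   keeps the beat minimum uniquely at the onset.
#' @return A `beat_template` list with landmark indices and values.
#' @export
beat_template <- function(duration, onset_value, sbp, fs = 125,
                          sp_frac = 0.20, dn_frac = 0.42, dn_level = 0.40,
                          bump_frac = 0.12, end_offset = 0.5) {
  if (duration < 0.5 || duration > 1.5) {
    stop("beat duration ", duration, " s outside the physiological range [0.5, 1.5] s")
  }
  stopifnot(sbp > onset_value)
  n <- round(duration * fs)
  sp_idx <- max(4L, round(sp_frac * n))
  dn_idx <- max(sp_idx + 4L, round(dn_frac * n))
  if (dn_idx > n - 6L) stop("beat too short to place a dicrotic notch")
  pp <- sbp - onset_value
  structure(
    list(duration = duration, fs = fs, n = n,
         onset_value = onset_value,
         systolic_peak = c(idx = sp_idx, value = sbp),
         dicrotic_notch = c(idx = dn_idx, value = onset_value + dn_level * pp),
         bump = bump_frac * pp, end_value = onset_value + end_offset),
    class = "beat_template"
  )
}

half_cos_rise <- function(from, to, len) {
  u <- seq(0, 1, length.out = len)
  from + (to - from) * (1 - cos(pi * u)) / 2
}

#' Render one ABP beat from a template
#'
#' The rendered waveform attains its minimum exactly at the onset sample
#' and its maximum exactly at the configured systolic-peak index; the
#' dicrotic notch is an exact local minimum at its configured index.
#'
#' @param template a [beat_template()].
#' @param fs sampling rate; must match the template's.
#' @return list with `samples` (mmHg) and `landmarks`
#'   (`onset_idx`, `sp_idx`, `dn_idx`, 1-based).
#' @export
synth_abp_beat <- function(template, fs = 125) {
  stopifnot(inherits(template, "beat_template"))
  if (fs != template$fs) stop("template was built for fs = ", template$fs)
  n <- template$n
  sp <- template$systolic_peak[["idx"]]
  dn <- template$dicrotic_notch[["idx"]]
  sbp <- template$systolic_peak[["value"]]
  dnv <- template$dicrotic_notch[["value"]]
  dp <- dn + max(3L, round(0.30 * (n - dn)))           # dicrotic bump peak
  dpv <- dnv + template$bump
  v <- numeric(n)
  v[1:sp] <- half_cos_rise(template$onset_value, sbp, sp)
  v[sp:dn] <- half_cos_rise(sbp, dnv, dn - sp + 1L)
  v[dn:dp] <- half_cos_rise(dnv, dpv, dp - dn + 1L)
  v[dp:n] <- half_cos_rise(dpv, template$end_value, n - dp + 1L)
  list(samples = v,
       landmarks = list(onset_idx = 1L, sp_idx = sp, dn_idx = dn))
}

apply_artifact <- function(x, spec, fs) {
  i0 <- max(1L, round(spec$start * fs) + 1L)
  i1 <- min(length(x), i0 + round(spec$duration * fs) - 1L)
  if (i1 < i0) stop("artifact interval outside the record")
  idx <- i0:i1
  x[idx] <- switch(spec$kind,
    flatline = x[i0],
    saturation_high = max(x),
    saturation_low = min(x),
    noise_burst = x[idx] + stats::rnorm(length(idx), 0, spec$level),
    stop("unknown artifact kind: ", spec$kind)
  )
  x
}

#' Specify an injectable artifact
#'
#' @param kind one of `"flatline"`, `"saturation_high"`, `"saturation_low"`,
#'   `"noise_burst"`.
#' @param start,duration interval in seconds.
#' @param level noise standard deviation for `noise_burst` (ignored
#'   otherwise).
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(kind, start, duration, level = 0) {
  structure(list(kind = kind, start = start, duration = duration,
                 level = level), class = "artifact_spec")
}

# Fixed ABP -> PPG transform: unit scaling, 80 ms delay, 2nd-order low-pass
# at 8 Hz (zero phase), x^0.9 nonlinearity after rescaling to [0, 1].
abp_to_ppg <- function(abp, fs) {
  p <- (abp - min(abp)) / (max(abp) - min(abp))
  d <- round(0.080 * fs)
  p <- c(rep(p[1], d), p[seq_len(length(p) - d)])
  bf <- signal::butter(2, 8 / (fs / 2), type = "low")
  p <- signal::filtfilt(bf, p)
  p <- (p - min(p)) / (max(p) - min(p))
  p^0.9
}

#' Generate a paired ABP/PPG record with ground truth
#'
#' Beats are drawn around the subject's baselines with multiplicative
#' jitter of at most 5% on period and amplitudes, rendered, and
#' concatenated; the PPG channel is produced by the fixed transform
#' described in [synthgen]. The ground-truth table lists every complete
#' beat's landmark sample indices (1-based, into the record) and its
#' per-beat DBP/SBP in mmHg.
#'
#' @param subject one-row tibble from [make_subject()].
#' @param duration record duration in seconds.
#' @param noise_sd additive Gaussian noise on the PPG channel
#'   (normalized units).
#' @param artifacts list of [artifact_spec()]s, applied to both channels.
#' @param seed integer seed; the same seed yields a bit-identical record.
#' @param fs sampling rate in Hz.
#' @param period_jitter,amp_jitter half-widths of the multiplicative
#'   beat-to-beat jitter on the heart period and on the pressure
#'   amplitudes (set both to 0 for perfectly repeated beats).
#' @return list with `record` (a `bp_record`) and `truth` (tibble with one
#'   row per beat: `onset_idx`, `sp_idx`, `dn_idx`, `dbp`, `sbp`,
#'   `duration`).
#' @export
synth_record <- function(subject, duration, noise_sd = 0, artifacts = list(),
                         seed = 1L, fs = 125, period_jitter = 0.05,
                         amp_jitter = 0.025) {
  set.seed(as.integer(seed))
  n_total <- round(duration * fs)
  abp <- numeric(0)
  rows <- list()
  onset <- 1L
  while (length(abp) < n_total) {
    per <- min(max(subject$mean_heart_period *
                     stats::runif(1, 1 - period_jitter, 1 + period_jitter),
                   0.5), 1.5)
    dbp_b <- subject$baseline_dbp * stats::runif(1, 1 - amp_jitter, 1 + amp_jitter)
    sbp_b <- subject$baseline_sbp * stats::runif(1, 1 - amp_jitter, 1 + amp_jitter)
    if (sbp_b - dbp_b <= 12) sbp_b <- dbp_b + 12
    tpl <- beat_template(per, dbp_b, sbp_b, fs = fs)
    beat <- synth_abp_beat(tpl, fs = fs)
    if (length(abp) + length(beat$samples) <= n_total) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        onset_idx = onset,
        sp_idx = onset + beat$landmarks$sp_idx - 1L,
        dn_idx = onset + beat$landmarks$dn_idx - 1L,
        dbp = dbp_b, sbp = sbp_b, duration = per
      )
    }
    abp <- c(abp, beat$samples)
    onset <- length(abp) + 1L
  }
  abp <- abp[seq_len(n_total)]
  ppg <- abp_to_ppg(abp, fs)
  if (noise_sd > 0) ppg <- ppg + stats::rnorm(n_total, 0, noise_sd)
  for (a in artifacts) {
    abp <- apply_artifact(abp, a, fs)
    ppg <- apply_artifact(ppg, a, fs)
  }
  rec <- bp_record(
    record_id = sprintf("%s-r%04d", subject$subject_id, as.integer(seed) %% 10000L),
    subject_id = subject$subject_id, fs = fs, abp = abp, ppg = ppg,
    age = subject$age, gender = subject$gender
  )
  list(record = rec, truth = dplyr::bind_rows(rows))
}
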