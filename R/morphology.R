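#' Onset-synchronize accepted pulses
#'
#' Stacks pulses into a matrix whose column `i` holds each pulse's value
#' `i - 1` samples after its onset; pulses shorter than a column contribute
#' `NA` there.
#'
#' @param pulses tibble from [delineate_pulses()] (needs the `samples`
#'   list-column), or a plain list of numeric vectors.
#' @return Numeric matrix, one row per pulse, `NA`-padded on the right.
#' @export
align_pulses <- function(pulses) {
  samples <- if (is.data.frame(pulses)) pulses$samples else pulses
  if (length(samples) < 2L) stop("averaging needs at least 2 pulses")
  len <- max(lengths(samples))
  do.call(rbind, lapply(samples, function(p) c(p, rep(NA_real_, len - length(p)))))
}

#' Ensemble-average with sigma-band point rejection
#'
#' Per time-step, the mean and population standard deviation are computed
#' over the contributing pulses; the reported value is the mean recomputed
#' using only contributors inside `mu +/- band_sd * sigma` (inclusive, so
#' zero-variance columns keep all contributors). The averaged pulse is
#' truncated to the median contributing pulse length, dropping the sparse
#' tail.
#'
#' @param aligned matrix from [align_pulses()].
#' @param band_sd rejection half-width in standard deviations.
#' @return list with `values` (the refined mean), `mu`, `sigma`, and
#'   `n_contributors` per step.
#' @export
average_pulse <- function(aligned, band_sd = 1.25) {
  lens <- apply(!is.na(aligned), 1L, sum)
  keep_len <- stats::median(lens)
  keep_len <- as.integer(floor(keep_len))
  cols <- seq_len(min(keep_len, ncol(aligned)))
  vals <- mu <- sigma <- nn <- numeric(length(cols))
  for (i in cols) {
    x <- aligned[, i]
    x <- x[!is.na(x)]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))            # population SD
    inside <- x >= m - band_sd * s & x <= m + band_sd * s
    vals[i] <- if (any(inside)) mean(x[inside]) else m
    mu[i] <- m; sigma[i] <- s; nn[i] <- length(x)
  }
  list(values = vals, mu = mu, sigma = sigma, n_contributors = nn)
}

#' Locate the systolic peak and dicrotic notch on an averaged pulse
#'
#' The systolic peak is the global maximum. The dicrotic notch is the most
#' prominent local minimum after the peak; when the post-peak limb is
#' monotone (no local minimum), the point of maximal curvature (largest
#' second difference) is used instead.
#'
#' @param avg_values numeric averaged pulse.
#' @return list with `sp_idx` and `dn_idx` (1-based).
#' @export
detect_landmarks <- function(avg_values) {
  n <- length(avg_values)
  sp <- which.max(avg_values)
  if (sp >= n - 2L) stop("no room after the systolic peak for a dicrotic notch")
  seg <- avg_values[(sp + 1L):n]
  m <- length(seg)
  # local minima: seg[i] < seg[i-1] and seg[i] <= seg[i+1], i in 2..m-1
  cand <- integer(0)
  if (m >= 3L) {
    i <- 2:(m - 1L)
    cand <- i[seg[i] < seg[i - 1L] & seg[i] <= seg[i + 1L]]
  }
  if (length(cand)) {
    prominence <- vapply(cand, function(i) {
      left <- max(seg[1:(i - 1L)])
      right <- max(seg[(i + 1L):m])
      min(left, right) - seg[i]
    }, numeric(1))
    dn <- cand[which.max(prominence)]
  } else {
    if (m < 3L) stop("post-peak limb too short to locate a dicrotic notch")
    curv <- diff(seg, differences = 2L)
    dn <- which.max(curv) + 1L             # curvature fallback
  }
  list(sp_idx = sp, dn_idx = sp + dn)
}

#' Assign cardiac-cycle classes to every time-step
#'
#' Steps up to and including the systolic peak are class 0
#' (onset-to-peak), steps after the peak up to and including the dicrotic
#' notch are class 1 (peak-to-notch), and the remainder is class 2
#' (notch-to-end). Class 3 (ended) only appears after homogenization.
#'
#' @param avg_values averaged pulse (only its length is used).
#' @param sp_idx,dn_idx landmark indices from [detect_landmarks()].
#' @return Integer vector of class codes 0/1/2.
#' @export
assign_classes <- function(avg_values, sp_idx, dn_idx) {
  n <- length(avg_values)
  if (!(sp_idx > 1L && sp_idx < dn_idx && dn_idx < n)) {
    stop("landmark ordering violated: need 1 < sp_idx < dn_idx < length")
  }
  cls <- integer(n)
  cls[(sp_idx + 1L):dn_idx] <- 1L
  cls[(dn_idx + 1L):n] <- 2L
  cls
}

#' Build an average-pulse morphology from a segment's accepted pulses
#'
#' @param pulses tibble from [delineate_pulses()].
#' @param fs sampling rate in Hz.
#' @param subject_id,segment_id identifiers carried into the result.
#' @param band_sd rejection band half-width.
#' @return A `bp_morphology` object: `values` (mmHg per step), `classes`
#'   (codes 0/1/2), `mu`, `sigma`, `sp_idx`, `dn_idx`, `duration` (s),
#'   `skewness`, plus identifiers.
#' @export
compute_morphology <- function(pulses, fs = 125, subject_id = NA_character_,
                               segment_id = NA_character_, band_sd = 1.25) {
  aligned <- align_pulses(pulses)
  avg <- average_pulse(aligned, band_sd = band_sd)
  lm <- detect_landmarks(avg$values)
  structure(
    list(values = avg$values,
         classes = assign_classes(avg$values, lm$sp_idx, lm$dn_idx),
         mu = avg$mu, sigma = avg$sigma,
         sp_idx = lm$sp_idx, dn_idx = lm$dn_idx,
         duration = length(avg$values) / fs, fs = fs,
         skewness = moment_skewness(avg$values),
         subject_id = subject_id, segment_id = segment_id),
    class = "bp_morphology"
  )
}

#' @export
print.bp_morphology <- function(x, ...) {
  cat(sprintf(
    "<bp_morphology %s/%s> %d steps (%.3f s), DBP %.1f SBP %.1f mmHg, SP@%d DN@%d\n",
    x$subject_id, x$segment_id, length(x$values), x$duration,
    min(x$values), max(x$values), x$sp_idx, x$dn_idx))
  invisible(x)
}

#' @export
as.data.frame.bp_morphology <- function(x, ...) {
  data.frame(step = seq_along(x$values) - 1L,
             time = (seq_along(x$values) - 1L) / x$fs,
             value = x$values, class = x$classes)
}

#' Dataset-level morphology filters
#'
#' Keeps morphologies whose maximum pressure does not exceed 180 mmHg,
#' whose duration does not exceed 1.2 s, and whose skewness exceeds 0.2.
#'
#' @param morphologies list of `bp_morphology` objects.
#' @param max_abp,max_duration,min_skewness overridable thresholds.
#' @return list with `kept` (the surviving morphologies) and `report`
#'   (tibble of per-morphology decisions and reasons).
#' @export
postfilter <- function(morphologies, max_abp = 180, max_duration = 1.2,
                       min_skewness = 0.2) {
  report <- purrr::map_dfr(morphologies, function(m) {
    reasons <- character(0)
    if (max(m$values) > max_abp) reasons <- c(reasons, "max_abp")
    if (m$duration > max_duration) reasons <- c(reasons, "duration")
    if (m$skewness <= min_skewness) reasons <- c(reasons, "skewness")
    tibble::tibble(subject_id = m$subject_id, segment_id = m$segment_id,
                   kept = length(reasons) == 0L,
                   reasons = paste(reasons, collapse = ","))
  })
  list(kept = morphologies[report$kept], report = report)
}

#' Cap the number of segments per subject
#'
#' Subjects holding more than `cap` segments are randomly subsampled down
#' to `cap`; all others are untouched.
#'
#' @param manifest tibble with at least `subject_id` and `segment_id`.
#' @param cap maximum segments per subject.
#' @param seed integer seed for the subsampling.
#' @return The capped manifest (row order preserved within subjects).
#' @export
cap_subject_segments <- function(manifest, cap = 10L, seed = 1L) {
  set.seed(as.integer(seed))
  manifest |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_sample(n = cap) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$segment_id)
}
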