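#' Prepare a raw PPG segment as a two-channel model input series
#'
#' Band-pass filters the 15-s raw PPG over `[0.5, 45]` Hz (4th-order
#' Butterworth, zero phase), computes its first time derivative with a
#' Savitzky-Golay filter (window 7, polynomial degree 3, analytic
#' first-derivative coefficients), and trims one second from each end to
#' discard filter edge artifacts, leaving a 13-s series.
#'
#' @param ppg_raw numeric vector of exactly `15 * fs` samples.
#' @param fs sampling rate in Hz.
#' @param band band-pass cutoffs in Hz.
#' @param sg_window,sg_degree Savitzky-Golay window length and degree.
#' @return Tibble with columns `ppg` and `dppg`, `13 * fs` rows.
#' @export
prepare_ppg_input <- function(ppg_raw, fs = 125, band = c(0.5, 45),
                              sg_window = 7L, sg_degree = 3L) {
  if (length(ppg_raw) != 15 * fs) {
    stop("expected a 15-s raw segment (", 15 * fs, " samples), got ",
         length(ppg_raw))
  }
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  ppg_f <- signal::filtfilt(bf, ppg_raw)
  dppg <- signal::sgolayfilt(ppg_f, p = sg_degree, n = sg_window, m = 1L,
                             ts = 1 / fs)
  trim <- fs                                # one second each end
  keep <- (trim + 1L):(length(ppg_f) - trim)
  tibble::tibble(ppg = ppg_f[keep], dppg = dppg[keep])
}

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps) stop("constant channel: cannot scale")
  (x - rng[1]) / diff(rng)
}

#' Draw a 5-s random model input window
#'
#' Uniform random start over the first 8 s of the prepared 13-s series;
#' both channels are independently MinMax-scaled to `[0, 1]` over the
#' window.
#'
#' @param prepared tibble from [prepare_ppg_input()].
#' @param seed integer seed; the same seed reproduces the same window.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds.
#' @return `window_s * fs` x 2 matrix (columns `ppg`, `dppg`), with the
#'   chosen start (samples, 0-based) as attribute `"start"`.
#' @export
sample_window <- function(prepared, seed = NULL, fs = 125, window_s = 5) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- window_s * fs
  max_start <- nrow(prepared) - L
  start <- sample.int(max_start + 1L, 1L) - 1L
  idx <- (start + 1L):(start + L)
  out <- cbind(ppg = minmax01(prepared$ppg[idx]),
               dppg = minmax01(prepared$dppg[idx]))
  attr(out, "start") <- start
  out
}

#' Global target scaler over a morphology collection
#'
#' A single affine map from the dataset-wide pressure range to `[0, 1]`;
#' fitted on the training set only and reused for test data.
#'
#' @param morphologies list of `bp_morphology` objects.
#' @return A `bp_scaler`: list with `min`, `max`, `transform(x)`,
#'   `inverse(x)`.
#' @export
scale_target_global <- function(morphologies) {
  vals <- unlist(purrr::map(morphologies, "values"))
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= .Machine$double.eps) stop("degenerate global pressure range")
  bp_scaler(lo, hi)
}

#' @rdname scale_target_global
#' @param lo,hi the global minimum / maximum in mmHg.
#' @export
bp_scaler <- function(lo, hi) {
  structure(
    list(min = lo, max = hi,
         transform = function(x) (x - lo) / (hi - lo),
         inverse = function(x) x * (hi - lo) + lo),
    class = "bp_scaler"
  )
}

#' Fixed homogenized target length
#'
#' The number of decoder steps: the longest pulse in the collection plus
#' `pad_steps` (0.12 s at 125 Hz).
#'
#' @param morphologies list of `bp_morphology` objects (or a vector of
#'   pulse lengths in steps).
#' @param pad_steps padding steps added to the maximum length.
#' @return Integer fixed length T.
#' @export
fixed_length <- function(morphologies, pad_steps = 15L) {
  lens <- if (is.numeric(morphologies)) morphologies
          else lengths(purrr::map(morphologies, "values"))
  stopifnot(length(lens) > 0)
  as.integer(max(lens) + pad_steps)
}

#' Homogenize one morphology to the fixed length
#'
#' Values are repeated cyclically until length `T`; classes keep their
#' original codes over the first copy and switch to the ended class (3)
#' afterwards; the mask is one over the first `len + pad_steps` steps
#' (truncated at `T`) and zero beyond.
#'
#' @param morphology a `bp_morphology` with values already scaled to
#'   `[0, 1]` (see [scale_target_global()]), or any list with `values` and
#'   `classes`.
#' @param T_len fixed length from [fixed_length()].
#' @param pad_steps mask padding beyond the true pulse.
#' @return list with `values`, `classes`, `mask` (each length `T_len`) and
#'   `true_len`.
#' @export
homogenize_target <- function(morphology, T_len, pad_steps = 15L) {
  v <- morphology$values
  cls <- morphology$classes
  len <- length(v)
  if (len > T_len) stop("morphology longer (", len, ") than fixed length ", T_len)
  reps <- rep_len(v, T_len)
  classes <- c(cls, rep(3L, T_len - len))
  mask <- c(rep(1, min(len + pad_steps, T_len)),
            rep(0, max(0L, T_len - len - pad_steps)))
  list(values = reps, classes = classes, mask = mask, true_len = len)
}

#' Encode the demographic input vector
#'
#' Age is scaled affinely from the `[18, 89]` analysis range to `[0, 1]`;
#' gender is a binary indicator (female = 0, male = 1).
#'
#' @param age years in `[18, 89]`.
#' @param gender `"female"` or `"male"`.
#' @return Numeric vector of length 2: `c(age_scaled, gender_code)`.
#' @export
encode_demographics <- function(age, gender) {
  if (is.na(age) || is.na(gender)) stop("missing demographics")
  stopifnot(age >= 18, age <= 89)
  gender <- match.arg(gender, c("female", "male"))
  c((age - 18) / (89 - 18), as.numeric(gender == "male"))
}
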