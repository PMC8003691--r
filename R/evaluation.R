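#' Restore scaled values to mmHg
#'
#' @param scaled numeric values in `[0, 1]` model units.
#' @param scaler a `bp_scaler` fitted on the training set.
#' @return Values in mmHg.
#' @export
restore_scale <- function(scaled, scaler) {
  stopifnot(inherits(scaler, "bp_scaler"))
  scaler$inverse(scaled)
}

#' Extract clinical markers from a predicted morphology
#'
#' The in-pulse region is every step before the first predicted ended
#' class. DBP is the mean of the first and last in-pulse value; SBP is the
#' in-pulse maximum; the dicrotic notch is the last step classified
#' peak-to-notch (class 1), its value read off the value sequence and its
#' time of occurrence (DNTO) given in ms; the pulse duration is the time
#' of the first ended step (full length when no ended class is predicted,
#' which is logged via the `complete` flag).
#'
#' @param values numeric value sequence in mmHg.
#' @param classes integer class codes 0-3 (e.g. argmax of the class-head
#'   probabilities).
#' @param fs sampling rate in Hz.
#' @return One-row tibble: `dbp`, `sbp`, `dn_value` (mmHg), `dnto`,
#'   `pulse_duration` (ms), `dn_found`, `complete`.
#' @export
extract_markers <- function(values, classes, fs = 125) {
  stopifnot(length(values) == length(classes))
  first_ed <- which(classes == 3L)[1]
  complete <- !is.na(first_ed)
  dur_steps <- if (complete) first_ed - 1L else length(values)
  # degenerate prediction opening with the ended class: keep one step so
  # the markers stay defined
  dur_steps <- max(dur_steps, 1L)
  in_pulse <- values[seq_len(dur_steps)]
  dn_steps <- which(classes[seq_len(dur_steps)] == 1L)
  dn_found <- length(dn_steps) > 0L
  dn_idx <- if (dn_found) dn_steps[length(dn_steps)] else NA_integer_
  tibble::tibble(
    dbp = (in_pulse[1] + in_pulse[length(in_pulse)]) / 2,
    sbp = max(in_pulse),
    dn_value = if (dn_found) values[dn_idx] else NA_real_,
    dnto = if (dn_found) (dn_idx - 1L) / fs * 1000 else NA_real_,
    pulse_duration = dur_steps / fs * 1000,
    dn_found = dn_found, complete = complete
  )
}

#' Scalar regression metrics
#'
#' RMSE, MAE, standard deviation of the errors (sample, n-1), coefficient
#' of determination, and Pearson correlation.
#'
#' @param truth,pred numeric vectors of equal length (n >= 2); when
#'   lengths differ, both are truncated to the shorter one.
#' @return One-row tibble: `rmse`, `mae`, `std`, `r2`, `r`, `n`.
#' @export
metrics <- function(truth, pred) {
  n <- min(length(truth), length(pred))
  stopifnot(n >= 2L)
  z <- truth[seq_len(n)]; zh <- pred[seq_len(n)]
  e <- z - zh
  if (stats::var(z) <= .Machine$double.eps) {
    stop("zero variance in truth: R2 and R undefined")
  }
  tibble::tibble(
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    std = stats::sd(e),
    r2 = 1 - sum(e^2) / sum((z - mean(z))^2),
    r = suppressWarnings(stats::cor(z, zh)),   # NA for constant predictions
    n = n
  )
}

#' Grade absolute errors against the BHS protocol
#'
#' Computes the cumulative percentage of absolute errors below 5, 10 and
#' 15 mmHg and assigns the best grade whose three thresholds are all met:
#' A (60/85/95), B (50/75/90), C (40/65/85), otherwise `"fail"`.
#'
#' @param abs_errors absolute errors in mmHg, or a 3-vector of
#'   already-computed cumulative percentages.
#' @param percentages logical; set `TRUE` when passing percentages.
#' @return list with `cumulative_pct` (named, `<5`, `<10`, `<15`) and
#'   `grade`.
#' @export
bhs_grade <- function(abs_errors, percentages = FALSE) {
  if (percentages) {
    stopifnot(length(abs_errors) == 3L)
    pct <- as.numeric(abs_errors)
  } else {
    stopifnot(length(abs_errors) > 0L)
    pct <- vapply(c(5, 10, 15),
                  function(th) 100 * mean(abs(abs_errors) < th), numeric(1))
  }
  rows <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "fail"
  for (g in c("C", "B", "A")) if (all(pct >= rows[[g]])) grade <- g
  list(cumulative_pct = stats::setNames(pct, c("<5", "<10", "<15")),
       grade = grade)
}

#' Bland-Altman agreement
#'
#' @param truth,pred paired measurements (n >= 2).
#' @return list with `mean_diff` and `limits`
#'   (`mean +/- 1.96 * sd` of the differences, sample sd).
#' @export
bland_altman <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2L)
  d <- pred - truth
  mu <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = mu, limits = c(lower = mu - 1.96 * s,
                                  upper = mu + 1.96 * s))
}

# Ground-truth markers of a (scaled or mmHg) morphology target.
truth_markers <- function(target, scaler = NULL, fs = 125) {
  v <- target$values[seq_len(target$true_len)]
  if (!is.null(scaler)) v <- restore_scale(v, scaler)
  extract_markers(
    c(v, rep(v[1], 1)),
    c(target$classes[seq_len(target$true_len)], 3L), fs)
}

#' Evaluate a trained model on a test set
#'
#' Runs autoregressive prediction for every test sample, restores physical
#' units with the training-set scaler, extracts markers from prediction
#' and ground truth, and computes marker metrics plus per-sample waveform
#' RMSE/MAE and Pearson R (each pair truncated to the shorter duration).
#'
#' @param model a trained `bp_seq2seq` with `scaler` and `fixed_length`
#'   set.
#' @param dataset a `bp_dataset` or list of samples (with `prepared`,
#'   `target`, optionally `x_di`).
#' @param seed seed for the evaluation window draws.
#' @return A `bp_evaluation`: list with `markers` (per-sample tibble of
#'   truth/predicted markers), `waveform` (per-sample tibble), and
#'   `summary` (marker x metric tibble).
#' @export
evaluate_model <- function(model, dataset, seed = 1L) {
  stopifnot(inherits(model, "bp_seq2seq"))
  scaler <- model$scaler
  if (is.null(scaler)) stop("model has no fitted target scaler")
  samples_raw <- if (inherits(dataset, "bp_dataset")) dataset$samples else dataset
  set.seed(as.integer(seed))
  per <- purrr::imap(samples_raw, function(s, j) {
    X <- if (!is.null(s$window)) s$window else sample_window(s$prepared)
    pred <- predict_sequence(model, X, s$x_di, model$fixed_length)
    pv <- restore_scale(pred$values, scaler)
    pm <- extract_markers(pv, pred$classes, fs = 125)
    tm <- truth_markers(s$target, scaler, fs = 125)
    tv <- restore_scale(s$target$values[seq_len(s$target$true_len)], scaler)
    nshort <- min(length(tv), round(pm$pulse_duration / 1000 * 125))
    nshort <- max(nshort, 2L)
    wf <- tibble::tibble(
      sample = j,
      r = suppressWarnings(stats::cor(tv[seq_len(nshort)], pv[seq_len(nshort)])),
      rmse = sqrt(mean((tv[seq_len(nshort)] - pv[seq_len(nshort)])^2)),
      mae = mean(abs(tv[seq_len(nshort)] - pv[seq_len(nshort)]))
    )
    list(markers = dplyr::bind_cols(
           tibble::tibble(sample = j),
           dplyr::rename_with(tm, ~ paste0("truth_", .x)),
           dplyr::rename_with(pm, ~ paste0("pred_", .x))),
         waveform = wf)
  })
  markers <- purrr::map_dfr(per, "markers")
  waveform <- purrr::map_dfr(per, "waveform")
  summarise_marker <- function(t, p) {
    ok <- !is.na(t) & !is.na(p)
    if (sum(ok) >= 2L && stats::var(t[ok]) > .Machine$double.eps)
      metrics(t[ok], p[ok])
    else tibble::tibble(rmse = NA_real_, mae = NA_real_, std = NA_real_,
                        r2 = NA_real_, r = NA_real_, n = sum(ok))
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarise_marker(markers$truth_dbp, markers$pred_dbp), marker = "DBP"),
    dplyr::mutate(summarise_marker(markers$truth_dn_value, markers$pred_dn_value), marker = "DN"),
    dplyr::mutate(summarise_marker(markers$truth_sbp, markers$pred_sbp), marker = "SBP"),
    dplyr::mutate(summarise_marker(markers$truth_dnto, markers$pred_dnto), marker = "DNTO"),
    dplyr::mutate(summarise_marker(markers$truth_pulse_duration,
                                   markers$pred_pulse_duration), marker = "duration"),
    tibble::tibble(rmse = mean(waveform$rmse), mae = mean(waveform$mae),
                   std = NA_real_, r2 = NA_real_,
                   r = mean(waveform$r, na.rm = TRUE),
                   n = nrow(waveform), marker = "waveform")
  ) |> dplyr::relocate("marker")
  structure(list(markers = markers, waveform = waveform, summary = summary),
            class = "bp_evaluation")
}

#' @export
print.bp_evaluation <- function(x, ...) {
  cat("<bp_evaluation>", nrow(x$markers), "test samples\n")
  print(x$summary)
  invisible(x)
}

#' Aggregate per-fold evaluations into a scenario report
#'
#' Mirrors the marker x metric layout of a cross-validated report: the
#' mean and standard deviation of every metric across folds.
#'
#' @param evaluations list of `bp_evaluation` objects, one per fold.
#' @param scenario scenario label carried into the report.
#' @return Tibble with `scenario`, `marker`, `metric`, `mean`, `sd`.
#' @export
evaluate_scenario <- function(evaluations, scenario = "Mixno") {
  purrr::imap_dfr(evaluations, function(ev, fold) {
    dplyr::mutate(ev$summary, fold = fold)
  }) |>
    tidyr::pivot_longer(cols = c("rmse", "mae", "std", "r2", "r"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$marker, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::mutate(scenario = scenario) |>
    dplyr::relocate("scenario")
}
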