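#' Tidy the training history of a fitted model
#'
#' @param x a `bp_seq2seq`.
#' @param ... unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `mse`, `ce`,
#'   `lr`.
#' @export
tidy.bp_seq2seq <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = numeric(),
                          mse = numeric(), ce = numeric(), lr = numeric()))
  }
  x$history
}

#' One-row model summary
#'
#' @param x a `bp_seq2seq`.
#' @param ... unused.
#' @return Tibble: parameter count, layer widths, DI flag, epochs trained,
#'   best loss.
#' @export
glance.bp_seq2seq <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x),
    enc_units = paste(x$arch$enc_units, collapse = "/"),
    dec_units = paste(x$arch$dec_units, collapse = "/"),
    use_di = x$arch$use_di,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_loss = if (is.null(x$best_loss)) NA_real_ else x$best_loss,
    fixed_length = if (is.null(x$fixed_length)) NA_integer_
                   else as.integer(x$fixed_length)
  )
}

#' Tidy an evaluation report
#'
#' @param x a `bp_evaluation`.
#' @param ... unused.
#' @return The marker-by-metric summary tibble.
#' @export
tidy.bp_evaluation <- function(x, ...) x$summary

#' One-row evaluation summary
#'
#' @param x a `bp_evaluation`.
#' @param ... unused.
#' @return Tibble with test-set size, waveform R, DBP/SBP MAE, and the BHS
#'   grades for DBP and SBP.
#' @export
glance.bp_evaluation <- function(x, ...) {
  g <- function(marker) {
    t <- x$markers[[paste0("truth_", marker)]]
    p <- x$markers[[paste0("pred_", marker)]]
    bhs_grade(abs(p - t))$grade
  }
  s <- x$summary
  pick <- function(mk, met) s[s$marker == mk, ][[met]]
  tibble::tibble(
    n = nrow(x$markers),
    waveform_r = pick("waveform", "r"),
    dbp_mae = pick("DBP", "mae"),
    sbp_mae = pick("SBP", "mae"),
    bhs_dbp = g("dbp"),
    bhs_sbp = g("sbp")
  )
}

#' Tidy a morphology into a per-step tibble
#'
#' @param x a `bp_morphology`.
#' @param ... unused.
#' @return Tibble: `step`, `time`, `value`, `class`, `mu`, `sigma`.
#' @export
tidy.bp_morphology <- function(x, ...) {
  tibble::tibble(step = seq_along(x$values) - 1L,
                 time = (seq_along(x$values) - 1L) / x$fs,
                 value = x$values, class = x$classes,
                 mu = x$mu, sigma = x$sigma)
}
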