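class_palette <- c(`0` = "#d73027", `1` = "#1a9850", `2` = "#4575b4",
                   `3` = "grey55")
class_labels <- c(`0` = "onset-peak", `1` = "peak-notch", `2` = "notch-end",
                  `3` = "ended")

#' Plot an average pulse morphology
#'
#' Values over time, colored by cardiac-cycle class, with the
#' mu +/- 1.25 sigma rejection band when available.
#'
#' @param object a `bp_morphology`.
#' @param band show the rejection band.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bp_morphology <- function(object, band = TRUE, ...) {
  df <- tidy(object)
  df$class <- factor(df$class, levels = names(class_labels),
                     labels = class_labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (band && !all(is.na(df$sigma))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mu - 1.25 * .data$sigma,
                   ymax = .data$mu + 1.25 * .data$sigma),
      fill = "grey85")
  }
  p + ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 1) +
    ggplot2::scale_colour_manual(values = unname(class_palette)[
      seq_along(levels(droplevels(df$class)))]) +
    ggplot2::labs(x = "time (s)", y = "ABP (mmHg)", colour = "class",
                  title = "Average ABP pulse morphology") +
    ggplot2::theme_minimal()
}

#' Plot a paired waveform record
#'
#' @param object a `bp_record`.
#' @param from,to optional time window in seconds.
#' @param ... unused.
#' @return A ggplot object with one facet per channel.
#' @export
autoplot.bp_record <- function(object, from = 0, to = NULL, ...) {
  df <- as.data.frame(object)
  if (is.null(to)) to <- max(df$time)
  df <- df[df$time >= from & df$time <= to, ]
  long <- tidyr::pivot_longer(df, c("abp", "ppg"), names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$record_id) +
    ggplot2::theme_minimal()
}

#' Plot a predicted sequence with its attention map
#'
#' @param prediction output of [predict_sequence()].
#' @param scaler optional `bp_scaler` to restore mmHg.
#' @param fs sampling rate.
#' @return A ggplot object (attention heat map).
#' @export
plot_attention <- function(prediction, scaler = NULL, fs = 125) {
  A <- prediction$attention
  df <- tidyr::expand_grid(step = seq_len(nrow(A)), source = seq_len(ncol(A)))
  df$weight <- as.vector(t(A))[(df$step - 1L) * ncol(A) + df$source]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source / fs,
                                   y = .data$step / fs,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "input time (s)", y = "output time (s)",
                  fill = "attention",
                  title = "Decoder attention over the PPG window") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for a marker
#'
#' @param evaluation a `bp_evaluation`.
#' @param marker `"dbp"` or `"sbp"`.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(evaluation, marker = "dbp") {
  t <- evaluation$markers[[paste0("truth_", marker)]]
  p <- evaluation$markers[[paste0("pred_", marker)]]
  ba <- bland_altman(t, p)
  df <- tibble::tibble(mean = (t + p) / 2, diff = p - t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "#4575b4") +
    ggplot2::geom_hline(yintercept = ba$limits, linetype = "dashed",
                        colour = "#d73027") +
    ggplot2::labs(x = sprintf("mean of reference and estimate (%s, mmHg)",
                              toupper(marker)),
                  y = "estimate - reference (mmHg)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}
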