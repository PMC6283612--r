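#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_vline labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' Plot a cleavage profile
#'
#' Raw per-position counts (columns) with the smoothed track overlaid, and
#' labelled peaks (if a `peak_set` is supplied) marked and annotated with
#' their stall-relative distance, mirroring the standard presentation of
#' stall-relative 3'-end maps.
#'
#' @param object A `cleavage_profile`.
#' @param peaks Optional `peak_set` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cleavage_profile <- function(object, peaks = NULL, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$distance)) +
    geom_col(aes(y = .data$count), width = 1, fill = "grey70") +
    labs(x = "distance upstream of stall (nt)", y = "fragment 3' ends",
         title = attr(object, "reporter_name")) +
    theme_minimal()
  if (!all(is.na(df$smoothed))) {
    p <- p + geom_line(aes(y = .data$smoothed), colour = "steelblue",
                       na.rm = TRUE)
  }
  if (!is.null(peaks)) {
    lab <- dplyr::filter(tidy(peaks), .data$labelled)
    if (nrow(lab)) {
      p <- p +
        geom_point(data = lab, aes(y = .data$height), colour = "firebrick") +
        ggplot2::geom_text(
          data = lab,
          aes(y = .data$height, label = .data$distance),
          vjust = -0.6, size = 3, colour = "firebrick"
        )
    }
  }
  p
}

#' Plot per-replicate shutoff decay fits
#'
#' Log-scale abundance against time with the fitted exponential per
#' replicate.
#'
#' @param object A `half_life_fit`.
#' @param course The decay course the fit was computed from (`replicate`,
#'   `time`, `abundance`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.half_life_fit <- function(object, course, ...) {
  stopifnot(all(c("replicate", "time", "abundance") %in% names(course)))
  ggplot(course, aes(x = .data$time, y = .data$abundance,
                     colour = .data$replicate)) +
    geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    labs(x = "time after shutoff (min)", y = "normalized abundance",
         subtitle = sprintf("t1/2 = %.1f %s min", object$mean,
                            if (!is.na(object$sd))
                              sprintf("± %.1f", object$sd) else "")) +
    theme_minimal()
}

#' Plot growth curves with their instantaneous-rate landmark
#'
#' OD600 and the smoothed first derivative for one or more curves; the
#' vertical line marks each curve's derivative argmax, whose separation
#' between conditions is the lag time.
#'
#' @param curves Tibble (`condition`, `time`, `od`) or a list of such tibbles.
#' @param smooth_k Moving-average window for [instantaneous_rate()].
#' @return A ggplot object of the derivative curves.
#' @export
plot_growth_rate <- function(curves, smooth_k = 5L) {
  if (!"condition" %in% names(curves)) curves$condition <- "curve"
  rates <- curves |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      r <- instantaneous_rate(df, smooth_k)
      tibble(time = r$time, rate = r$rate,
             argmax_time = attr(r, "argmax_time"))
    }) |>
    dplyr::ungroup()
  ggplot(rates, aes(x = .data$time, y = .data$rate,
                    colour = .data$condition)) +
    geom_line() +
    geom_vline(aes(xintercept = .data$argmax_time,
                   colour = .data$condition),
               linetype = "dashed", show.legend = FALSE) +
    labs(x = "time (h)", y = "dOD/dt (per h)") +
    theme_minimal()
}
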