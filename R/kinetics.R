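#' Fit mRNA half-lives from a transcriptional-shutoff course
#'
#' Per replicate, fits a least-squares line through (time, ln abundance); the
#' half-life is `ln(2) / |slope|`. This log-linear fit is exact on noiseless
#' exponential decay and is the standard quantification for shutoff Northern
#' time courses. Replicates with a non-decaying (zero or positive) slope are
#' flagged and excluded from the summary with a warning. The summary is the
#' mean and SD over the per-replicate half-lives.
#'
#' @param course Tibble with columns `replicate`, `time` (minutes) and
#'   `abundance` (normalized signal, positive). Non-positive abundances are
#'   dropped with a warning.
#' @return A `half_life_fit` object; see [tidy.half_life_fit()] and
#'   [glance.half_life_fit()].
#' @export
#' @examples
#' course <- simulate_decay_course(10, c(0, 10, 20), noise_cv = 0, n_reps = 1)
#' glance(fit_half_life(course))$mean_t_half  # 10
fit_half_life <- function(course) {
  stopifnot(all(c("replicate", "time", "abundance") %in% names(course)))
  if (any(course$abundance <= 0, na.rm = TRUE)) {
    warning("dropping ", sum(course$abundance <= 0, na.rm = TRUE),
            " non-positive abundance value(s) before log-linear fitting")
    course <- dplyr::filter(course, .data$abundance > 0)
  }
  per_rep <- course |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        stop("replicate '", key$replicate,
             "' has fewer than 2 usable timepoints", call. = FALSE)
      }
      fit <- stats::lm(log(abundance) ~ time, data = df)
      slope <- unname(stats::coef(fit)[2L])
      tibble(slope = slope,
             t_half = if (slope < 0) log(2) / abs(slope) else NA_real_,
             non_decaying = slope >= 0,
             n_timepoints = nrow(df))
    }) |>
    dplyr::ungroup()
  if (all(per_rep$non_decaying)) {
    stop("no replicate shows decay; half-life is undefined", call. = FALSE)
  }
  if (any(per_rep$non_decaying)) {
    warning(sum(per_rep$non_decaying),
            " non-decaying replicate(s) excluded from the half-life summary")
  }
  ok <- per_rep$t_half[!per_rep$non_decaying]
  structure(
    list(replicates = per_rep,
         mean = mean(ok),
         sd = if (length(ok) >= 2L) stats::sd(ok) else NA_real_,
         n_used = length(ok)),
    class = "half_life_fit"
  )
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat("<half_life_fit> t1/2 = ", signif(x$mean, 3),
      if (!is.na(x$sd)) paste0(" ± ", signif(x$sd, 2)), " min (",
      x$n_used, " replicate(s))\n", sep = "")
  invisible(x)
}

#' Instantaneous growth rate of an OD curve
#'
#' Centered moving-average smoothing of the OD series (k points) followed by
#' central differences, the numerical first derivative of the growth curve.
#' The maximum of this series is the maximal instantaneous growth rate and
#' its time (the argmax) is the landmark used for lag comparisons. Ties are
#' broken toward the earliest time and flagged.
#'
#' @param curve Tibble with columns `time` (hours, increasing) and `od`.
#' @param smooth_k Moving-average window (points, default 5; ~50 min at
#'   10-min sampling).
#' @return A tibble `time`, `rate` at interior timepoints, with attributes
#'   `argmax_time`, `max_rate` and `tied_max`.
#' @export
instantaneous_rate <- function(curve, smooth_k = 5L) {
  stopifnot(all(c("time", "od") %in% names(curve)))
  t <- curve$time
  od <- curve$od
  if (is.unsorted(t, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  smooth_k <- as.integer(smooth_k)
  if (length(t) < smooth_k + 2L) {
    stop("need at least smooth_k + 2 timepoints", call. = FALSE)
  }
  s <- as.numeric(stats::filter(od, rep(1 / smooth_k, smooth_k), sides = 2))
  n <- length(s)
  rate <- rep(NA_real_, n)
  rate[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  keep <- !is.na(rate)
  out <- tibble(time = t[keep], rate = rate[keep])
  mx <- max(out$rate)
  at <- which(out$rate == mx)
  structure(out,
            argmax_time = out$time[at[1L]],
            max_rate = mx,
            tied_max = length(at) > 1L)
}

#' Lag time between two growth curves
#'
#' The separation between the times at which the two curves reach their
#' maximal instantaneous growth rate: `lag = argmax-time(test) -
#' argmax-time(reference)`, positive when the test culture lags the
#' reference. Antisymmetric by construction.
#'
#' @param reference,test Growth-curve tibbles (`time`, `od`).
#' @param smooth_k Moving-average window passed to [instantaneous_rate()].
#' @return Lag in hours (a single number). Tied derivative maxima resolve to
#'   the earliest time with a warning.
#' @export
#' @examples
#' a <- simulate_growth_curve(lag_shift = 0)
#' b <- simulate_growth_curve(lag_shift = 2)
#' lag_time(a, b)  # ~2 h
lag_time <- function(reference, test, smooth_k = 5L) {
  r <- instantaneous_rate(reference, smooth_k)
  s <- instantaneous_rate(test, smooth_k)
  if (attr(r, "tied_max") || attr(s, "tied_max")) {
    warning("tied derivative maxima; using the earliest time")
  }
  attr(s, "argmax_time") - attr(r, "argmax_time")
}

#' Polysome/monosome peak-height ratio from an A254 trace
#'
#' Baseline-corrected peak-height ratio of a sucrose-gradient absorbance
#' trace: within each region the baseline is the trace minimum (the valleys
#' flanking the peak inside the region window) and the peak height is the
#' maximum above that baseline. The ratio polysome/monosome is a proxy for
#' global ribosome engagement.
#'
#' @param trace Tibble with columns `position` (increasing; larger = heavier)
#'   and `a254`.
#' @param monosome_region,polysome_region Length-2 numeric `c(lo, hi)` region
#'   bounds on `position`; must not overlap and must lie within the trace.
#' @return The ratio (single number).
#' @export
polysome_monosome_ratio <- function(trace, monosome_region, polysome_region) {
  stopifnot(all(c("position", "a254") %in% names(trace)),
            length(monosome_region) == 2L, length(polysome_region) == 2L)
  if (is.unsorted(trace$position, strictly = TRUE)) {
    stop("trace positions must be increasing", call. = FALSE)
  }
  if (monosome_region[1L] <= polysome_region[2L] &&
      polysome_region[1L] <= monosome_region[2L]) {
    stop("monosome and polysome regions must not overlap", call. = FALSE)
  }
  height <- function(region) {
    inr <- trace$position >= region[1L] & trace$position <= region[2L]
    if (!any(inr)) stop("region outside the trace", call. = FALSE)
    y <- trace$a254[inr]
    max(y) - min(y)
  }
  mono <- height(monosome_region)
  poly <- height(polysome_region)
  if (mono <= 0) {
    stop("monosome peak height is not positive; ratio undefined", call. = FALSE)
  }
  poly / mono
}
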