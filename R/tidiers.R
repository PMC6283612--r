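#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cleavage profile
#'
#' @param x A `cleavage_profile`.
#' @param ... Unused.
#' @return A plain tibble, one row per position (`distance`, `count`,
#'   `smoothed`).
#' @export
tidy.cleavage_profile <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row profile summary
#'
#' @param x A `cleavage_profile`.
#' @param ... Unused.
#' @return Tibble: `reporter_name`, `window`, `n_fragments`, `overflow`,
#'   `smoothed` (whether the smoothed track is present).
#' @export
glance.cleavage_profile <- function(x, ...) {
  m <- profile_meta(x)
  tibble(reporter_name = m$reporter_name, window = nrow(x),
         n_fragments = m$n_fragments, overflow = m$overflow,
         smoothed = !is.null(m$smoothing))
}

#' Tidy a peak set
#'
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return Tibble `distance`, `height`, `labelled`.
#' @export
tidy.peak_set <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row peak-set summary
#'
#' Includes the spacing/periodicity statistics of the labelled peaks.
#'
#' @param x A `peak_set`.
#' @param ... Unused.
#' @return Tibble: `threshold`, `n_candidates`, plus [peak_spacing_stats()]
#'   columns.
#' @export
glance.peak_set <- function(x, ...) {
  dplyr::bind_cols(
    tibble(threshold = attr(x, "threshold"), n_candidates = nrow(x)),
    peak_spacing_stats(x)
  )
}

#' Per-replicate half-life estimates
#'
#' @param x A `half_life_fit`.
#' @param ... Unused.
#' @return Tibble: `replicate`, `slope`, `t_half`, `non_decaying`,
#'   `n_timepoints`.
#' @export
tidy.half_life_fit <- function(x, ...) {
  x$replicates
}

#' Half-life summary (mean ± SD over replicates)
#'
#' @param x A `half_life_fit`.
#' @param ... Unused.
#' @return Tibble: `mean_t_half`, `sd_t_half`, `n_replicates`, `n_excluded`.
#' @export
glance.half_life_fit <- function(x, ...) {
  tibble(mean_t_half = x$mean, sd_t_half = x$sd, n_replicates = x$n_used,
         n_excluded = sum(x$replicates$non_decaying))
}
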