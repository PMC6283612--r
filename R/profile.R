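#' Build a stall-relative cleavage profile
#'
#' Tallies fragment 3'-end distances upstream of the stall into a per-position
#' histogram over the analysis window `1..upstream_window`. Each fragment is
#' one count -- no collapsing. Distances beyond the window are counted in an
#' overflow tally; non-positive distances are an error (ends at or downstream
#' of the stall belong in the flagged bin of [map_reads()], not here).
#'
#' @param distances Positive integer upstream distances (nt), e.g. the
#'   `distance_upstream` column of mapped fragments.
#' @param upstream_window Window size in nt (default 600).
#' @param reporter_name Label carried in the profile.
#' @return A `cleavage_profile`: a tibble with columns `distance` (1..window),
#'   `count` and `smoothed` (NA until [smooth_profile()]), with attributes
#'   `reporter_name`, `n_fragments` (in-window total) and `overflow`.
#' @export
#' @examples
#' build_histogram(c(150, 150, 150), upstream_window = 200)
build_histogram <- function(distances, upstream_window = 600L,
                            reporter_name = NA_character_) {
  distances <- as.integer(distances[!is.na(distances)])
  if (any(distances <= 0L)) {
    stop("upstream distances must be positive; ends at or downstream of the ",
         "stall are excluded from the profile", call. = FALSE)
  }
  upstream_window <- as.integer(upstream_window)
  in_window <- distances <= upstream_window
  counts <- tabulate(distances[in_window], nbins = upstream_window)
  out <- tibble(
    distance = seq_len(upstream_window),
    count = as.integer(counts),
    smoothed = NA_real_
  )
  new_cleavage_profile(out, reporter_name = reporter_name,
                       n_fragments = sum(in_window),
                       overflow = sum(!in_window))
}

new_cleavage_profile <- function(df, reporter_name, n_fragments, overflow,
                                 smoothing = NULL, peaks = NULL) {
  structure(
    df,
    class = c("cleavage_profile", class(tibble())),
    reporter_name = reporter_name,
    n_fragments = as.integer(n_fragments),
    overflow = as.integer(overflow),
    smoothing = smoothing
  )
}

profile_meta <- function(profile) {
  list(reporter_name = attr(profile, "reporter_name"),
       n_fragments = attr(profile, "n_fragments"),
       overflow = attr(profile, "overflow"),
       smoothing = attr(profile, "smoothing"))
}

#' @export
print.cleavage_profile <- function(x, ...) {
  m <- profile_meta(x)
  cat("<cleavage_profile>",
      if (!is.na(m$reporter_name)) paste0(" ", m$reporter_name), "\n", sep = "")
  cat("  window      : 1..", nrow(x), " nt upstream of stall\n", sep = "")
  cat("  fragments   : ", m$n_fragments, " in window, ", m$overflow,
      " beyond\n", sep = "")
  if (!is.null(m$smoothing)) {
    cat("  smoothing   : Savitzky-Golay, window ", m$smoothing$window,
        ", order ", m$smoothing$order, "\n", sep = "")
  }
  NextMethod()
}

#' Savitzky-Golay smoothing of a cleavage profile
#'
#' Adds the smoothed track: at each position the value of the least-squares
#' polynomial of the given order fitted to the counts over the centered
#' window (the classic "5-point quadratic polynomial" with the defaults).
#' Positions within `(window - 1) / 2` of the profile edges lack a full
#' window and carry `NA` -- values are never extrapolated there, so edge
#' artifacts cannot seed peaks.
#'
#' @param profile A `cleavage_profile` from [build_histogram()].
#' @param window Odd window length in points (default 5).
#' @param order Polynomial order, `< window` (default 2).
#' @return The profile with its `smoothed` column filled.
#' @export
smooth_profile <- function(profile, window = 5L, order = 2L) {
  stopifnot(inherits(profile, "cleavage_profile"))
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (order >= window) stop("order must be smaller than window", call. = FALSE)
  if (nrow(profile) < window) {
    stop("profile shorter than the smoothing window", call. = FALSE)
  }
  coefs <- signal::sgolay(p = order, n = window)[(window + 1L) / 2L, ]
  sm <- stats::filter(profile$count, coefs, sides = 2)
  m <- profile_meta(profile)
  profile$smoothed <- as.numeric(sm)
  new_cleavage_profile(profile, reporter_name = m$reporter_name,
                       n_fragments = m$n_fragments, overflow = m$overflow,
                       smoothing = list(window = window, order = order))
}

#' Call and label peaks on a smoothed profile
#'
#' Candidate peaks are local maxima of the smoothed track: positions strictly
#' greater than both neighbours, with plateaus (runs of equal values flanked
#' by strictly smaller ones) reduced to their most-upstream position.
#' Candidates must have positive smoothed height; counts are non-negative, so
#' a non-positive bump is a smoothing side-lobe artifact, not a cleavage
#' signal. The labelling threshold is the `peak_quantile` quantile (linear
#' interpolation between order statistics) of the smoothed values -- over the
#' whole analysis window by default, or over candidate peak heights with
#' `threshold_on = "peaks"`. A candidate is labelled iff its height is at or
#' above the threshold.
#'
#' @param profile A smoothed `cleavage_profile`.
#' @param peak_quantile Quantile for the labelling threshold (default 0.75).
#' @param threshold_on `"window"` (quantile over all smoothed values in the
#'   window, the default) or `"peaks"` (over candidate heights only).
#' @return A `peak_set`: tibble `distance`, `height`, `labelled`, sorted by
#'   increasing distance, with attribute `threshold`.
#' @export
call_peaks <- function(profile, peak_quantile = 0.75,
                       threshold_on = c("window", "peaks")) {
  stopifnot(inherits(profile, "cleavage_profile"),
            peak_quantile >= 0, peak_quantile <= 1)
  threshold_on <- match.arg(threshold_on)
  v <- profile$smoothed
  if (all(is.na(v))) {
    stop("profile has no smoothed track; run smooth_profile() first",
         call. = FALSE)
  }
  idx <- which(!is.na(v))
  x <- v[idx]
  n <- length(x)
  cand <- integer(0)
  if (n >= 3L) {
    i <- 2L
    while (i <= n - 1L) {
      if (x[i] > x[i - 1L]) {
        j <- i
        while (j < n && x[j + 1L] == x[i]) j <- j + 1L
        # run i..j of equal values; peak if it falls off after the run
        if (j < n && x[j + 1L] < x[i]) {
          cand <- c(cand, j)  # most-upstream position of the plateau
          i <- j + 1L
        } else {
          i <- j + 1L
        }
      } else {
        i <- i + 1L
      }
    }
  }
  heights <- x[cand]
  keep <- heights > 0
  cand <- cand[keep]
  heights <- heights[keep]
  threshold <- if (threshold_on == "window") {
    if (all(x == 0)) 0 else profile_quantile(x, peak_quantile)
  } else {
    if (length(heights) == 0L) 0 else profile_quantile(heights, peak_quantile)
  }
  out <- tibble(
    distance = profile$distance[idx][cand],
    height = heights,
    labelled = heights >= threshold
  )
  out <- dplyr::arrange(out, .data$distance)
  structure(out, class = c("peak_set", class(tibble())),
            threshold = as.numeric(threshold),
            peak_quantile = peak_quantile, threshold_on = threshold_on)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", sum(x$labelled), " labelled / ", nrow(x),
      " candidate peaks, threshold ", signif(attr(x, "threshold"), 4),
      " (quantile ", attr(x, "peak_quantile"), ", over ",
      attr(x, "threshold_on"), ")\n", sep = "")
  NextMethod()
}

#' Spacing and periodicity statistics of labelled peaks
#'
#' Consecutive differences between labelled peak distances summarise the
#' cleavage periodicity: the ~30-nt ladder of a stacked ribosome queue, or
#' the ~45-nt rhythm of cleavage-runoff cycles. The modal spacing is the most
#' frequent spacing after rounding to the nearest nt (ties broken toward the
#' smaller value). With fewer than two labelled peaks the spacing statistics
#' are `NA` and `degenerate` is `TRUE`.
#'
#' @param peaks A `peak_set` from [call_peaks()].
#' @return One-row tibble: `n_labelled`, `modal_spacing`, `median_spacing`,
#'   `span`, `degenerate`.
#' @export
#' @examples
#' # labelled peaks at 15/45/75 nt -> 30-nt periodicity over a 60-nt span
peak_spacing_stats <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  d <- sort(peaks$distance[peaks$labelled])
  n <- length(d)
  if (n < 2L) {
    return(tibble(n_labelled = n, modal_spacing = NA_real_,
                  median_spacing = NA_real_,
                  span = if (n == 1L) 0 else NA_real_,
                  degenerate = TRUE))
  }
  sp <- round(diff(d))
  tab <- table(sp)
  modal <- min(as.numeric(names(tab)[tab == max(tab)]))
  tibble(n_labelled = n, modal_spacing = modal,
         median_spacing = stats::median(sp),
         span = max(d) - min(d), degenerate = FALSE)
}

#' Write a cleavage profile to TSV
#'
#' One row per position (`distance_upstream`, `raw_count`, `smoothed_value`,
#' `labelled_peak`), preceded by `#`-prefixed metadata lines so the file
#' round-trips losslessly through [read_profile()].
#'
#' @param profile A `cleavage_profile`.
#' @param path Output path.
#' @param peaks Optional `peak_set`; its labelled distances set the
#'   `labelled_peak` flag (all `FALSE` otherwise).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, peaks = NULL) {
  stopifnot(inherits(profile, "cleavage_profile"))
  m <- profile_meta(profile)
  labelled <- if (!is.null(peaks)) {
    profile$distance %in% peaks$distance[peaks$labelled]
  } else rep(FALSE, nrow(profile))
  header <- c(
    paste0("# reporter_name=", m$reporter_name),
    paste0("# n_fragments=", m$n_fragments),
    paste0("# overflow=", m$overflow),
    if (!is.null(m$smoothing)) {
      paste0("# smoothing=", m$smoothing$window, ",", m$smoothing$order)
    }
  )
  body <- tibble(
    distance_upstream = profile$distance,
    raw_count = profile$count,
    smoothed_value = profile$smoothed,
    labelled_peak = labelled
  )
  writeLines(header, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a cleavage profile written by [write_profile()]
#'
#' @param path TSV path.
#' @return A `cleavage_profile` (the `labelled_peak` flag is returned as an
#'   extra column `labelled`).
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "# ")]
  kv <- sub("^# ", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  body <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  df <- tibble(
    distance = as.integer(body$distance_upstream),
    count = as.integer(body$raw_count),
    smoothed = as.numeric(body$smoothed_value),
    labelled = as.logical(body$labelled_peak)
  )
  smoothing <- NULL
  if (!is.null(meta$smoothing)) {
    parts <- as.integer(strsplit(meta$smoothing, ",")[[1L]])
    smoothing <- list(window = parts[1L], order = parts[2L])
  }
  rn <- meta$reporter_name %||% NA_character_
  if (identical(rn, "NA")) rn <- NA_character_
  new_cleavage_profile(df, reporter_name = rn,
                       n_fragments = as.integer(meta$n_fragments %||% sum(df$count)),
                       overflow = as.integer(meta$overflow %||% 0L),
                       smoothing = smoothing)
}
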