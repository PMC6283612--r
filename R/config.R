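#' Analysis configuration
#'
#' Bundles the tunable parameters shared by trimming, alignment, profiling and
#' peak calling. Defaults encode the library chemistry and figure conventions
#' of the 3'-RACE NGD mapping experiment: the ligated DNA adapter
#' `CTGTAGGCACCATCAAT`, a 5-point quadratic (Savitzky-Golay) smoother, a 75%
#' quantile peak-labelling threshold and a 600-nt stall-relative analysis
#' window.
#'
#' @param adapter 3' adapter sequence ligated to fragment ends.
#' @param min_overlap Minimum read-suffix/adapter-prefix overlap (nt) for a
#'   trim to be accepted.
#' @param max_mismatch_frac Maximum mismatch fraction tolerated in the
#'   adapter match.
#' @param max_align_mismatches Maximum Hamming distance for an accepted
#'   reporter placement.
#' @param min_fragment_length Minimum trimmed length (nt) submitted to the
#'   aligner.
#' @param smoothing_window Odd Savitzky-Golay window length (points).
#' @param smoothing_order Polynomial order of the smoother (must be smaller
#'   than the window).
#' @param peak_quantile Quantile (in `[0, 1]`) of smoothed values at or above
#'   which candidate peaks are labelled.
#' @param upstream_window Analysis window: distances 1..`upstream_window` nt
#'   upstream of the stall.
#' @param seed Integer seed for any stochastic step.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(adapter = "CTGTAGGCACCATCAAT",
                            min_overlap = 6L,
                            max_mismatch_frac = 0.1,
                            max_align_mismatches = 2L,
                            min_fragment_length = 15L,
                            smoothing_window = 5L,
                            smoothing_order = 2L,
                            peak_quantile = 0.75,
                            upstream_window = 600L,
                            seed = 1L) {
  adapter <- toupper(adapter)
  stopifnot(
    grepl("^[ACGT]+$", adapter),
    min_overlap >= 1L,
    max_mismatch_frac >= 0, max_mismatch_frac < 1,
    max_align_mismatches >= 0L,
    min_fragment_length >= 1L,
    peak_quantile >= 0, peak_quantile <= 1,
    upstream_window >= 1L
  )
  smoothing_window <- as.integer(smoothing_window)
  smoothing_order <- as.integer(smoothing_order)
  if (smoothing_window %% 2L != 1L) {
    stop("smoothing_window must be odd", call. = FALSE)
  }
  if (smoothing_order >= smoothing_window) {
    stop("smoothing_order must be smaller than smoothing_window", call. = FALSE)
  }
  structure(
    list(adapter = adapter,
         min_overlap = as.integer(min_overlap),
         max_mismatch_frac = max_mismatch_frac,
         max_align_mismatches = as.integer(max_align_mismatches),
         min_fragment_length = as.integer(min_fragment_length),
         smoothing_window = smoothing_window,
         smoothing_order = smoothing_order,
         peak_quantile = peak_quantile,
         upstream_window = as.integer(upstream_window),
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat("  ", format(k, width = 22), x[[k]], "\n", sep = "")
  invisible(x)
}
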