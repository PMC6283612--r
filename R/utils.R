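#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange count summarise group_by ungroup
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic generators in the package funnel through this, so a given
# seed yields identical output regardless of surrounding RNG use.
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Quantile convention used everywhere: linear interpolation between order
# statistics (stats::quantile type 7), fixed so thresholds reproduce bit for
# bit.
profile_quantile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE)
}
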