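# Independent brute-force oracles. These deliberately re-derive each result
# from first principles (loops, lm fits, direct quantiles) and share no code
# with the implementation they check.

# Adapter trimming: try every adapter start position in the read, longest
# qualifying match (full internal adapter, or a 3'-terminal partial overlap
# of length >= min_overlap) wins.
oracle_trim <- function(read, adapter, min_overlap = 6L, max_mismatch_frac = 0.1) {
  rch <- strsplit(read, "")[[1]]
  ach <- strsplit(adapter, "")[[1]]
  lr <- length(rch); la <- length(ach)
  best <- NA_character_
  for (p in seq_len(lr)) {
    alen <- min(la, lr - p + 1L)
    is_partial <- alen < la
    if (is_partial && alen < min_overlap) next
    mm <- sum(rch[p:(p + alen - 1L)] != ach[seq_len(alen)])
    if (mm <= floor(max_mismatch_frac * alen)) {
      best <- substr(read, 1L, p - 1L)
      break  # smallest p == longest removed stretch
    }
  }
  best
}

# Ungapped placement: full Hamming scan over every offset.
oracle_align <- function(trimmed, ref, max_mismatches = 2L) {
  tch <- strsplit(trimmed, "")[[1]]
  rch <- strsplit(ref, "")[[1]]
  L <- length(tch)
  n_off <- length(rch) - L + 1L
  if (n_off < 1L) return(NULL)
  dists <- vapply(seq_len(n_off), function(s) {
    sum(tch != rch[s:(s + L - 1L)])
  }, numeric(1))
  best <- min(dists)
  if (best > max_mismatches) return(list(why = "too_many_mismatches"))
  at <- which(dists == best)
  if (length(at) > 1L) return(list(why = "ambiguous"))
  list(start = at, end3 = at + L - 1L, mismatches = best)
}

# Savitzky-Golay check: explicit least-squares polynomial fit per window,
# evaluated at the window centre.
oracle_sg <- function(counts, window = 5L, order = 2L) {
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  out <- rep(NA_real_, n)
  x <- seq.int(-half, half)
  for (i in (half + 1L):(n - half)) {
    y <- counts[(i - half):(i + half)]
    fit <- stats::lm(y ~ stats::poly(x, order, raw = TRUE))
    out[i] <- unname(predict(fit, newdata = data.frame(x = 0)))
  }
  out
}

# Peak scan: position-by-position local-maximum test (plateaus -> their
# largest-distance edge, positive height required) plus a direct type-7
# quantile threshold.
oracle_peaks <- function(smoothed, peak_quantile = 0.75) {
  idx <- which(!is.na(smoothed))
  x <- smoothed[idx]
  n <- length(x)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    # left neighbour strictly smaller (skipping backwards over equal run)
    l <- i - 1L
    while (l >= 1L && x[l] == x[i]) l <- l - 1L
    r <- i + 1L
    if (l < 1L || x[l] >= x[i]) next
    if (x[r] >= x[i]) next  # plateau edge: next value must drop
    cand <- c(cand, i)
  }
  cand <- cand[x[cand] > 0]
  thr <- if (all(x == 0)) 0 else
    stats::quantile(x, peak_quantile, type = 7, names = FALSE)
  list(distance = idx[cand], height = x[cand],
       labelled = x[cand] >= thr, threshold = thr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small reporter used across mapping tests: random 600-nt sequence, stall at
# 400, primer at 50 (synthetic geometry, scaled down from the full layout).
tiny_reporter <- function(seed = 11) {
  withr::with_seed(seed, reporter_spec(
    name = "tiny", sequence = random_dna(600), stall_start = 400L,
    stall_type = "SL", primer_start = 50L))
}

ADAPTER <- "CTGTAGGCACCATCAAT"
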