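test_that("histogram counts conserve fragments and match a direct tally", {
  empty <- build_histogram(integer(0), upstream_window = 100)
  expect_true(all(empty$count == 0))
  expect_identical(attr(empty, "n_fragments"), 0L)

  three <- build_histogram(c(150, 150, 150), upstream_window = 600)
  expect_identical(three$count[three$distance == 150], 3L)
  expect_identical(sum(three$count), 3L)
  expect_identical(attr(three, "n_fragments"), 3L)

  withr::with_seed(5, {
    d <- sample(1:700, 500, replace = TRUE)
  })
  prof <- build_histogram(d, upstream_window = 600)
  # independent counting oracle
  for (pos in unique(d[d <= 600])) {
    expect_identical(prof$count[prof$distance == pos], sum(d == pos))
  }
  expect_identical(attr(prof, "overflow"), sum(d > 600))
  expect_identical(attr(prof, "n_fragments") + attr(prof, "overflow"), 500L)

  expect_error(build_histogram(c(5, 0)), "positive")
  expect_error(build_histogram(c(5, -3)), "positive")
})

test_that("smoothing reproduces polynomials and the impulse closed form", {
  const <- build_histogram(rep(1:9, each = 4), upstream_window = 9)
  # constant counts: smoother returns the constant at interior positions
  sm <- smooth_profile(const, 5, 2)
  expect_equal(sm$smoothed[3:7], rep(4, 5))
  expect_true(all(is.na(sm$smoothed[c(1, 2, 8, 9)])))

  # linear ramp reproduced exactly
  ramp <- build_histogram(rep(1:10, times = 1:10), upstream_window = 10)
  smr <- smooth_profile(ramp, 5, 2)
  expect_equal(smr$smoothed[3:8], as.numeric(3:8))

  # unit impulse: centre value is 17/35
  imp <- build_histogram(3, upstream_window = 5)
  smi <- smooth_profile(imp, 5, 2)
  expect_equal(smi$smoothed[3], 17 / 35)

  expect_error(smooth_profile(build_histogram(1, upstream_window = 3), 5, 2),
               "shorter")
  expect_error(smooth_profile(const, 4, 2), "odd")
  expect_error(smooth_profile(const, 5, 5), "order")
})

test_that("smoothing equals an explicit least-squares fit on random profiles", {
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      counts <- rpois(n, lambda = sample(1:20, 1))
      prof <- build_histogram(rep(seq_len(n), counts), upstream_window = n)
      sm <- smooth_profile(prof, 5, 2)
      expect_equal(sm$smoothed, oracle_sg(prof$count, 5, 2), tolerance = 1e-9)
    }
  })
})

test_that("smoothing is a linear operator", {
  withr::with_seed(12, {
    for (i in 1:10) {
      n <- 40
      x <- rpois(n, 5); y <- rpois(n, 5)
      a <- runif(1, 0.5, 3); b <- runif(1, 0.5, 3)
      smooth_counts <- function(v) {
        p <- build_histogram(integer(0), upstream_window = n)
        p$count <- as.integer(round(v))  # integer track for histogram class
        smooth_profile(p, 5, 2)$smoothed
      }
      # linearity holds on the raw numeric track
      coefs <- signal::sgolay(2, 5)[3, ]
      f <- function(v) as.numeric(stats::filter(v, coefs, sides = 2))
      expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-9)
      expect_equal(smooth_counts(x), f(x), tolerance = 1e-12)
    }
  })
})

test_that("peak calling matches the brute-force scan and labels by quantile", {
  # strictly increasing track: no interior local maxima
  inc <- build_histogram(rep(1:10, times = 1:10), upstream_window = 10) |>
    smooth_profile()
  expect_identical(nrow(call_peaks(inc)), 0L)

  # single interior maximum above threshold: exactly one labelled peak
  single <- build_histogram(rep(c(2, 5, 8), times = c(2, 30, 2)),
                            upstream_window = 9) |> smooth_profile()
  pk <- call_peaks(single)
  expect_identical(sum(pk$labelled), 1L)
  expect_identical(pk$distance[pk$labelled], 5L)

  # two bumps, one below the 75% window quantile
  counts <- c(0, 0, 2, 30, 2, 0, 0, 0, 1, 4, 1, 0, 0, 0)
  prof <- build_histogram(rep(seq_along(counts), counts),
                          upstream_window = length(counts)) |> smooth_profile()
  pk2 <- call_peaks(prof, peak_quantile = 0.75)
  orc <- oracle_peaks(prof$smoothed, 0.75)
  expect_identical(pk2$distance, as.integer(orc$distance))
  expect_equal(pk2$height, orc$height)
  expect_identical(pk2$labelled, orc$labelled)
  expect_equal(attr(pk2, "threshold"), orc$threshold)
  expect_identical(sum(pk2$labelled), 1L)   # the small bump is unlabelled
  expect_identical(nrow(pk2), 2L)

  # all-zero smoothed track: empty peak set, threshold 0
  zero <- build_histogram(integer(0), upstream_window = 20) |> smooth_profile()
  pz <- call_peaks(zero)
  expect_identical(nrow(pz), 0L)
  expect_identical(attr(pz, "threshold"), 0)

  expect_error(call_peaks(build_histogram(1:3, upstream_window = 10)),
               "smoothed")
})

test_that("peak calling agrees with the oracle on random profiles", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(20:80, 1)
      counts <- rpois(n, lambda = runif(1, 0.5, 10))
      prof <- build_histogram(rep(seq_len(n), counts), upstream_window = n) |>
        smooth_profile()
      q <- sample(c(0.5, 0.75, 0.9), 1)
      got <- call_peaks(prof, peak_quantile = q)
      want <- oracle_peaks(prof$smoothed, q)
      expect_identical(got$distance, as.integer(want$distance))
      expect_identical(got$labelled, want$labelled)
      expect_equal(attr(got, "threshold"), want$threshold)
    }
  })
})

test_that("raising the labelling quantile never adds labelled peaks", {
  withr::with_seed(23, {
    counts <- rpois(120, 4)
  })
  prof <- build_histogram(rep(1:120, counts), upstream_window = 120) |>
    smooth_profile()
  qs <- seq(0, 1, by = 0.05)
  n_labelled <- vapply(qs, function(q) {
    sum(call_peaks(prof, peak_quantile = q)$labelled)
  }, numeric(1))
  expect_true(all(diff(n_labelled) <= 0))

  # the candidate-height thresholding variant obeys the same monotonicity
  n_lab_pk <- vapply(qs, function(q) {
    sum(call_peaks(prof, peak_quantile = q, threshold_on = "peaks")$labelled)
  }, numeric(1))
  expect_true(all(diff(n_lab_pk) <= 0))
})

test_that("plateaus are reduced to their most-upstream position", {
  # craft the smoothed track directly: flat top at distances 5..7
  p <- build_histogram(integer(0), upstream_window = 11) |> smooth_profile()
  p$smoothed <- c(NA, NA, 1, 2, 4, 4, 4, 2, 1, NA, NA)
  pk <- call_peaks(p)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$distance, 7L)  # largest distance of the plateau
  expect_identical(pk$height, 4)

  # a plateau running into the track edge is not a peak
  p$smoothed <- c(NA, NA, 1, 2, 4, 4, 4, 4, 4, NA, NA)
  expect_identical(nrow(call_peaks(p)), 0L)

  # the oracle applies the same convention
  orc <- oracle_peaks(c(NA, NA, 1, 2, 4, 4, 4, 2, 1, NA, NA))
  expect_identical(orc$distance, 7L)
})

test_that("spacing statistics summarise labelled-peak periodicity", {
  fake_peaks <- function(distances) {
    structure(tibble::tibble(distance = distances,
                             height = rep(1, length(distances)),
                             labelled = TRUE),
              class = c("peak_set", class(tibble::tibble())),
              threshold = 0, peak_quantile = 0.75, threshold_on = "window")
  }
  s <- peak_spacing_stats(fake_peaks(c(15, 45, 75)))
  expect_identical(s$modal_spacing, 30)
  expect_identical(s$median_spacing, 30)
  expect_identical(s$span, 60)
  expect_false(s$degenerate)

  s2 <- peak_spacing_stats(fake_peaks(c(45, 90, 135, 150)))
  expect_identical(s2$modal_spacing, 45)

  # tie in spacing frequencies resolves to the smaller spacing
  s3 <- peak_spacing_stats(fake_peaks(c(10, 40, 55)))  # spacings 30, 15
  expect_identical(s3$modal_spacing, 15)

  s1 <- peak_spacing_stats(fake_peaks(150))
  expect_identical(s1$n_labelled, 1L)
  expect_true(is.na(s1$modal_spacing))
  expect_identical(s1$span, 0)
  expect_true(s1$degenerate)

  s0 <- peak_spacing_stats(fake_peaks(numeric(0)))
  expect_identical(s0$n_labelled, 0L)
  expect_true(s0$degenerate)
})
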