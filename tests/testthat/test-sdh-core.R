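test_that("quantization is an exact linear map with bounded round-off", {
  expect_equal(quantize(c(0, 2.5, 5), bin_width = 2.5)$levels, c(0L, 1L, 2L))
  expect_equal(quantize(rep(3.7, 10))$levels, rep(0L, 10))

  withr::with_seed(1, x <- runif(100, 0, 10))
  q <- quantize(x, bin_width = 0.1)
  expect_lte(max(abs(dequantize(q) - x)), 0.05)

  expect_error(quantize(c(1, NA)), "non-finite")
  expect_error(quantize(numeric(0)), "empty")
  expect_error(quantize(1:3, bin_width = 0), "positive")
})

test_that("sum and difference vectors pair each point with its M-lagged neighbour", {
  p <- sum_diff_vectors(c(1, 2, 4, 2, 1), M = 1)
  expect_equal(p$sum, c(3L, 6L, 6L, 3L))
  expect_equal(p$diff, c(1L, 2L, -2L, -1L))

  const <- sum_diff_vectors(rep(4L, 6), M = 2)
  expect_true(all(const$diff == 0L))
  expect_true(all(const$sum == 8L))

  alt <- sum_diff_vectors(c(0, 1, 0, 1, 0, 1), M = 1)
  expect_equal(alt$diff, c(1L, -1L, 1L, -1L, 1L))

  expect_error(sum_diff_vectors(1:3, M = 3), "M")
})

test_that("windowed histograms are normalized counts over contiguous windows", {
  p <- sum_diff_vectors(c(1, 2, 4, 2, 1), M = 1) # diff = 1, 2, -2, -1
  h <- window_histograms(p, N = 4)
  expect_length(h, 1L)
  expect_equal(h[[1]]$diff_values, c(-2L, -1L, 1L, 2L))
  expect_equal(h[[1]]$diff_prob, rep(0.25, 4))
  expect_equal(sum(h[[1]]$diff_prob), 1, tolerance = 1e-12)
  expect_equal(sum(h[[1]]$sum_prob), 1, tolerance = 1e-12)

  # window count = floor((len - N)/stride) + 1
  long <- sum_diff_vectors(rep_len(0:5, 452), M = 1) # len 451
  expect_length(window_histograms(long, N = 149, stride = 1), 303L)
  expect_length(window_histograms(long, N = 451), 1L)
  expect_length(window_histograms(long, N = 50, stride = 25), 17L)
  expect_error(window_histograms(long, N = 452), "N")
})

test_that("contrast and homogeneity match hand-computed values", {
  h1 <- hist_pair(diff = c(`-2` = 1 / 4, `-1` = 1 / 4, `1` = 1 / 4, `2` = 1 / 4))
  expect_equal(contrast(h1), 2.5)
  expect_equal(homogeneity(h1), 5 / 12)
  expect_equal(homogeneity(h1, kernel = "squared"), (1 / 5 + 1 / 2 + 1 / 2 + 1 / 5) / 4)

  h2 <- hist_pair(diff = c(`1` = 3 / 5, `-1` = 2 / 5))
  expect_equal(contrast(h2), 1.0)
  expect_equal(homogeneity(h2), 0.5)

  h0 <- hist_pair(diff = c(`0` = 1))
  expect_equal(contrast(h0), 0)
  expect_equal(homogeneity(h0), 1)
})

test_that("the nine features are exact on enumerable windows", {
  # constant signal at level c: single-support histograms
  p <- sum_diff_vectors(rep(7L, 20), M = 1)
  f <- texture_features(window_histograms(p, N = 19)[[1]])
  expect_equal(f$mean, 7)
  expect_equal(f$variance, 0)
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$cluster_shade, 0)
  expect_equal(f$cluster_prominence, 0)

  # V = (1, 2, 3): hS = {3: 1/2, 5: 1/2}, hD = {1: 1}
  f2 <- texture_features(window_histograms(sum_diff_vectors(1:3, 1), N = 2)[[1]])
  expect_equal(f2$mean, 2)
  expect_equal(f2$contrast, 1)
  expect_equal(f2$homogeneity, 0.5)
  expect_equal(f2$energy, 0.5)
  expect_equal(f2$entropy, log(2))

  # symmetric sum histogram about 2*mu has zero third central moment
  sym <- hist_pair(diff = c(`0` = 1), sum = c(`2` = 1 / 4, `4` = 1 / 2, `6` = 1 / 4))
  expect_equal(texture_features(sym)$cluster_shade, 0)
})

test_that("features equal the brute-force multiset oracle on random signals", {
  withr::with_seed(42, {
    for (i in 1:120) {
      n <- sample(10:50, 1)
      v <- sample(0:8, n, replace = TRUE)
      M <- sample(1:3, 1)
      N <- sample(2:(n - M), 1)
      kernel <- sample(c("abs", "squared"), 1)
      expected <- oracle_features(v, M, N, stride = 1, kernel = kernel)

      pair <- sum_diff_vectors(v, M)
      wins <- window_histograms(pair, N)
      got <- do.call(rbind, lapply(wins, function(h)
        as.data.frame(texture_features(h, kernel = kernel))))
      expect_equal(got, expected, tolerance = 1e-10, ignore_attr = TRUE)

      # every emitted histogram is normalized
      for (h in wins) {
        expect_equal(sum(h$sum_prob), 1, tolerance = 1e-12)
        expect_equal(sum(h$diff_prob), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("moment identity: contrast equals variance minus correlation", {
  withr::with_seed(7, {
    for (i in 1:25) {
      v <- sample(0:10, 40, replace = TRUE)
      f <- texture_features(window_histograms(sum_diff_vectors(v, 1), N = 30)[[1]])
      expect_equal(f$contrast, f$variance - f$correlation, tolerance = 1e-12)
    }
  })
})

test_that("sinusoid contrast approaches its closed form under fine quantization", {
  A <- 5; f <- 5; fs <- 40; bw <- 0.01
  t <- (0:2399) / fs # 60 s, 300 tremor periods
  x <- A * sin(2 * pi * f * t)
  pair <- sum_diff_vectors(quantize(x, bin_width = bw), M = 1)
  h <- window_histograms(pair, N = length(pair$diff))[[1]]
  expect_equal(contrast(h) * bw^2, 2 * A^2 * sin(pi * f / fs)^2, tolerance = 0.05)
})

test_that("contrast grows and homogeneity shrinks with oscillation amplitude", {
  f <- 5; fs <- 40
  t <- (0:599) / fs
  phi <- 0.3
  for (A in c(0.5, 1, 2, 4)) {
    h1 <- window_histograms(sum_diff_vectors(quantize(A * sin(2 * pi * f * t + phi),
                                                      0.1), 1), N = 300)
    h2 <- window_histograms(sum_diff_vectors(quantize(2 * A * sin(2 * pi * f * t + phi),
                                                      0.1), 1), N = 300)
    for (w in seq_along(h1)) {
      expect_gt(contrast(h2[[w]]), contrast(h1[[w]]))
      expect_lt(homogeneity(h2[[w]]), homogeneity(h1[[w]]))
    }
  }
})

test_that("difference-histogram features are invariant to a constant offset", {
  withr::with_seed(12, x <- cumsum(rnorm(200)))
  for (shift in c(-50, 13.7)) {
    h0 <- window_histograms(sum_diff_vectors(quantize(x, 0.1), 1), N = 100)
    h1 <- window_histograms(sum_diff_vectors(quantize(x + shift, 0.1), 1), N = 100)
    for (w in seq_along(h0)) {
      expect_equal(contrast(h1[[w]]), contrast(h0[[w]]))
      expect_equal(homogeneity(h1[[w]]), homogeneity(h0[[w]]))
    }
  }
})

test_that("per-recording extraction yields one feature row per window", {
  rec <- simulate_recording(1, "right", seed = 8) # 600 samples
  f <- sdh_features(rec, N = 149)
  expect_equal(nrow(f), 451L) # floor((600 - 1 - 149)/1) + 1
  expect_identical(setdiff(names(f), c("window", "start")),
                   c("mean", "variance", "energy", "correlation", "entropy",
                     "contrast", "homogeneity", "cluster_shade",
                     "cluster_prominence"))
  expect_error(sdh_features(rec, N = 600), "too short")

  # multi-channel: 9 features per channel, prefixed, in requested order
  f3 <- sdh_features(rec, channels = palm_channels(), N = 599)
  expect_equal(nrow(f3), 1L)
  feat_cols <- setdiff(names(f3), c("window", "start"))
  expect_length(feat_cols, 27L)
  expect_true(all(startsWith(feat_cols[1:9], "palm_pos_x_")))

  # fast path agrees with the histogram-object path
  h <- window_histograms(sum_diff_vectors(quantize(rec$palm_pos_x, 0.1), 1), N = 149)
  expect_equal(f$contrast[10], contrast(h[[10]]), tolerance = 1e-12)
  expect_equal(f$homogeneity[200], homogeneity(h[[200]]), tolerance = 1e-12)
})
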