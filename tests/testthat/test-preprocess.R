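# Segmentation, normalization and the synthetic record generator.

test_that("z-score uses the population convention and is idempotent", {
  expect_equal(zscore_epoch(c(1, 2, 3)),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  z <- zscore_epoch(rand_epoch(500, 1))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(zscore_epoch(z), z, tolerance = 1e-12)
  expect_error(zscore_epoch(rep(2, 100)), "flatline|zero-variance")
})

test_that("z-score is invariant to positive affine rescaling", {
  for (i in 1:20) {
    x <- rand_epoch(200, 300 + i)
    a <- runif(1, 0.1, 10)
    b <- rnorm(1, sd = 5)
    expect_equal(zscore_epoch(a * x + b), zscore_epoch(x),
                 tolerance = 1e-10)
  }
})

test_that("segmentation matches brute-force windowing for random durations", {
  set.seed(42)
  for (i in 1:20) {
    fs <- sample(c(100, 128, 250), 1)
    dur <- runif(1, 100, 2000)
    n <- round(dur * fs)
    rec <- ecg_record(list(CH1 = rnorm(n)), fs)
    win <- round(300 * fs)
    expected <- floor(n / win)
    expect_equal(epoch_count(n, fs), expected)
    eps <- suppressWarnings(segment_record(rec))
    expect_length(eps, expected)
    if (expected > 0) {
      # brute force: epoch k must be exactly the k-th window
      k <- sample(expected, 1)
      expect_equal(eps[[k]]$samples,
                   rec$channels$CH1[((k - 1) * win + 1):(k * win)])
    }
  }
})

test_that("the cohort-scale record arithmetic holds", {
  # 2 h 10 min 12 s at 128 Hz = 999936 samples -> 26 five-minute epochs
  expect_equal(epoch_count(999936, 128), 26L)
  rec <- synthesize_ecg_record("LRHT", duration_s = 7812, seed = 3)
  expect_equal(rec$n_samples, 999936L)
  eps <- segment_record(rec)
  expect_length(eps, 26L * 3L)
  expect_equal(sum(vapply(eps, function(e) e$channel == "CH1", logical(1))),
               26L)
})

test_that("records shorter than one window yield no epochs, with a warning", {
  rec <- ecg_record(list(CH1 = rnorm(1000)), 128)
  expect_warning(eps <- segment_record(rec), "shorter")
  expect_length(eps, 0)
})

test_that("the synthetic generator is deterministic and structurally sound", {
  r1 <- synthesize_ecg_record("HRHT", duration_s = 400, seed = 7)
  r2 <- synthesize_ecg_record("HRHT", duration_s = 400, seed = 7)
  expect_identical(r1$channels, r2$channels)
  expect_named(r1$channels, c("CH1", "CH2", "CH3"))
  expect_equal(r1$class_label, "HRHT")
  r3 <- synthesize_ecg_record("HRHT", duration_s = 400, seed = 8)
  expect_false(identical(r1$channels$CH1, r3$channels$CH1))
})

test_that("a noise-free 60 bpm record is exactly periodic at 128 samples", {
  rec <- synthesize_ecg_record(duration_s = 300, heart_rate_bpm = 60,
                               noise_sd = 0, seed = 1)
  x <- rec$channels$CH3
  n <- length(x)
  expect_equal(x[1:(n - 128)], x[129:n], tolerance = 1e-12)
  expect_gt(max(abs(x)), 0)
})

test_that("generator rejects invalid profiles and restores the RNG state", {
  expect_error(synthesize_ecg_record(duration_s = 100), "300")
  expect_error(synthesize_ecg_record(heart_rate_bpm = -10), "positive")
  expect_error(synthesize_ecg_record(noise_sd = -1), "nonnegative")
  set.seed(99)
  before <- .Random.seed
  invisible(synthesize_ecg_record(duration_s = 300, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("record constructor enforces channel consistency", {
  expect_error(ecg_record(list(CH1 = rnorm(10), CH2 = rnorm(9)), 128),
               "equal length")
  expect_error(ecg_record(list(), 128), "non-empty")
  expect_error(ecg_record(list(CH1 = rnorm(10)), -1), "positive")
})
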