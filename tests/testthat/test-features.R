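# Log-energy and fractal-dimension features.

test_that("log-energy is exact on hand-computable bands", {
  expect_equal(log_energy(c(3, 4)), log(25))
  expect_equal(log_energy(rep(1, 10)), log(10))
  expect_equal(log_energy(c(1, 0, 0)), 0)
  expect_equal(log_energy(c(3, 4), base = "ten"), log10(25))
  expect_error(log_energy(rep(0, 5)), "all-zero")
  expect_error(log_energy(numeric(0)), "non-empty")
})

test_that("smooth and flat signals have fractal dimension near one", {
  expect_equal(fractal_dimension(seq(0, 1, length.out = 1024)), 1,
               tolerance = 0.05)
  expect_equal(fractal_dimension(rep(2.5, 1024)), 1, tolerance = 0.05)
  expect_equal(fractal_dimension(sin(seq(0, 2 * pi, length.out = 2048))), 1,
               tolerance = 0.06)
})

test_that("rough traces recover the theoretical graph dimension 2 - H", {
  x <- fbm_midpoint(4096, hurst = 0.5, seed = 21)
  expect_lt(abs(fractal_dimension(x) - 1.5), 0.1)
})

test_that("rougher traces score higher than smoother ones", {
  d_rough <- fractal_dimension(fbm_midpoint(4096, 0.3, seed = 31))
  d_smooth <- fractal_dimension(fbm_midpoint(4096, 0.8, seed = 32))
  expect_gt(d_rough, d_smooth)
})

test_that("the dimension estimate is amplitude-scale invariant", {
  x <- fbm_midpoint(2048, 0.5, seed = 41)
  d0 <- fractal_dimension(x)
  for (c in c(0.5, 2, 10))
    expect_lt(abs(fractal_dimension(c * x) - d0), 0.02)
})

test_that("alternative estimators agree on the smooth-curve limit", {
  line <- seq(0, 1, length.out = 1024)
  expect_equal(fractal_dimension(line, method = "katz"), 1, tolerance = 0.05)
  expect_equal(fractal_dimension(line, method = "higuchi"), 1,
               tolerance = 0.05)
})

test_that("bands too short for the scale set are rejected", {
  expect_error(fractal_dimension(rnorm(32)), "64")
  expect_error(fractal_dimension(c(rnorm(100), NA, rnorm(30))), "non-finite")
})

test_that("band log-energies add up to the epoch energy (orthonormality)", {
  fb <- test_bank()
  x <- zscore_epoch(rand_epoch(4096, 51))
  sbs <- subband_decompose(x, fb)
  loge <- vapply(sbs$bands, log_energy, numeric(1))
  expect_equal(sum(exp(loge)), sum(x^2), tolerance = 1e-6)
})

test_that("the feature table has one row and twelve features per epoch", {
  fb <- test_bank()
  eps <- lapply(1:3, function(i) zscore_epoch(rand_epoch(2048, 60 + i)))
  ft <- feature_table(eps, fb)
  expect_equal(nrow(ft), 3L)
  expect_true(all(feature_names() %in% names(ft)))
  expect_length(feature_names(), 12L)
  expect_true(all(is.finite(as.matrix(ft[, feature_names()]))))
  # determinism: a duplicated epoch gives an identical feature row
  ft2 <- feature_table(list(eps[[1]], eps[[1]]), fb)
  expect_equal(ft2[1, feature_names()], ft2[2, feature_names()],
               ignore_attr = TRUE)
})

test_that("rescaling an epoch shifts log-energies and leaves dimensions", {
  fb <- test_bank()
  x <- rand_epoch(2048, 71)
  f1 <- feature_table(list(x), fb)
  f2 <- feature_table(list(2 * x), fb)
  loge_cols <- grep("^LOGE_", feature_names(), value = TRUE)
  sfd_cols <- grep("^SFD_", feature_names(), value = TRUE)
  expect_equal(as.numeric(f2[, loge_cols]) - as.numeric(f1[, loge_cols]),
               rep(log(4), 6), tolerance = 1e-9)
  expect_equal(as.numeric(f2[, sfd_cols]), as.numeric(f1[, sfd_cols]),
               tolerance = 0.02)
})

test_that("failing epochs are skipped with identification, others survive", {
  fb <- test_bank()
  eps <- list(zscore_epoch(rand_epoch(2048, 81)),
              rnorm(100),  # not divisible by 2^5 -> decomposition error
              zscore_epoch(rand_epoch(2048, 82)))
  expect_warning(ft <- feature_table(eps, fb), "skipped 1")
  expect_equal(nrow(ft), 2L)
})
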