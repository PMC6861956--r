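# The SDP-designed product filter and its spectral factorization.

test_that("MSSL objective weights follow the closed-form pattern", {
  expect_equal(mssl_weights(2), c(pi^2 / 3, -4))
  expect_equal(mssl_weights(4), c(pi^2 / 3, -4, 0, -4 / 9))
  s8 <- mssl_weights(8)
  expect_equal(s8[c(2, 4, 6, 8)], -4 / c(1, 3, 5, 7)^2)
  expect_equal(s8[c(3, 5, 7)], rep(0, 3))
  expect_error(mssl_weights(3), "even")
  expect_error(mssl_weights(0), "even")
})

test_that("linear objective equals the spectral second moment (Haar oracle)", {
  # independent oracle: sigma_f^2 = (1/pi) int_0^pi f^2 (1 + cos f) df
  oracle <- integrate(function(f) f^2 * (1 + cos(f)), 0, pi,
                      rel.tol = 1e-13)$value / pi
  expect_equal(sum(mssl_weights(2) * c(1, 0.5)), oracle, tolerance = 1e-9)
  expect_equal(oracle, pi^2 / 3 - 2, tolerance = 1e-12)
})

test_that("shortest design is the Haar bank, fully determined", {
  d <- design_product_filter(design_spec(2, 1))
  expect_equal(d$pf$p, c(1, 0.5), tolerance = 1e-10)
  expect_equal(d$certificate$objective_value, pi^2 / 3 - 2,
               tolerance = 1e-9)
  fb <- spectral_factorize(d$pf, design_spec(2, 1))
  expect_equal(fb$a0, c(1, 1) / sqrt(2), tolerance = 1e-9)
})

test_that("N=4, M=2 constraints pin down the maximal-regularity solution", {
  # with N=4, M=2 the half-band plus regularity equations determine p by a
  # 2x2 linear solve: p(1) = 9/16, p(3) = -1/16
  d <- design_product_filter(design_spec(4, 2))
  expect_equal(d$pf$p, c(1, 9 / 16, 0, -1 / 16), tolerance = 1e-9)
})

test_that("factorizing the N=4 product filter recovers the known 4-tap filter", {
  fb <- spectral_factorize(daubechies_product_filter(4), design_spec(4, 2))
  ref <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  err <- min(max(abs(fb$a0 - ref)), max(abs(rev(fb$a0) - ref)),
             max(abs(fb$a0 + ref)), max(abs(rev(fb$a0) + ref)))
  expect_lt(err, 1e-8)
  # its two alternating-moment residuals vanish
  m <- 0:3
  expect_lt(abs(sum((-1)^m * fb$a0)), 1e-10)
  expect_lt(abs(sum((-1)^m * m * fb$a0)), 1e-10)
})

test_that("relaxing regularity can only improve the spectral localization", {
  for (n in c(6, 8, 16)) {
    d <- design_product_filter(design_spec(n, 2))
    daub <- sum(mssl_weights(n) * daubechies_product_filter(n)$p)
    expect_lte(d$certificate$objective_value, daub + 1e-9)
  }
})

test_that("designed banks satisfy every defining identity", {
  configs <- list(c(2, 1), c(4, 2), c(6, 2), c(8, 3), c(16, 4))
  f <- seq(0, pi, length.out = 1025)
  for (cfg in configs) {
    n <- cfg[1]; m <- cfg[2]
    fb <- owfb(n, m)
    v <- verify_filterbank(fb)
    expect_lt(v$halfband_residual, 1e-8)
    expect_lt(v$pr_residual, 1e-8)
    expect_lt(v$orthonormality_residual, 1e-8)
    expect_lt(max(abs(v$zm_residuals)), 1e-8)
    expect_lt(v$unit_energy_residual, 1e-10)
    expect_equal(sum(fb$a0), sqrt(2), tolerance = 1e-9)
    # linear objective vs independent adaptive quadrature
    expect_lt(abs(v$mssl_by_quadrature - fb$achieved_mssl), 1e-9)
    # factorization consistency: autocorrelation reproduces p
    expect_lt(max(abs(owfb:::autocorrelation(fb$a0) - fb$pf$p)), 1e-8)
    # half-band identity on the grid
    spec <- product_spectrum(fb$pf, f)
    expect_lt(max(abs(spec + rev(spec) - 2)), 1e-8)
    expect_gte(min(spec), -1e-8)
    # certificate: PSD and trace map
    Z <- fb$certificate$Z
    expect_gte(min(eigen(Z, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    p_from_z <- vapply(0:(n - 1), function(k)
      sum(owfb:::diag_sum_mat(n, k) * Z), numeric(1))
    expect_lt(max(abs(p_from_z - fb$pf$p)), 1e-9)
    expect_equal(fb$certificate$solver_status, "optimal")
    # optimality sandwich against the maximal-regularity filter
    daub <- sum(mssl_weights(n) * daubechies_product_filter(n)$p)
    expect_lte(fb$achieved_mssl, daub + 1e-9)
  }
})

test_that("product spectrum evaluation and its domain checks", {
  haar <- product_filter(c(1, 0.5))
  expect_equal(product_spectrum(haar, 0), 2)
  expect_equal(product_spectrum(haar, pi), 0, tolerance = 1e-15)
  expect_error(product_spectrum(haar, -0.1), "\\[0, pi\\]")
  expect_error(product_spectrum(haar, pi + 0.1), "\\[0, pi\\]")
})

test_that("invalid design specs are rejected with the violated family named", {
  expect_error(design_spec(7, 2), "even")
  expect_error(design_spec(8, 5), "regularity")
  expect_error(design_spec(8, 0), "positive integer")
  expect_error(design_spec(8, 2, psd_epsilon = -1), "nonnegative")
  expect_error(design_spec(8, 2, solver_tolerance = 0), "positive")
})

test_that("product filter constructor validates its invariants", {
  expect_error(product_filter(c(2, 0.5)), "p\\(0\\)")
  expect_error(product_filter(c(1, 0.2, 0.3, 0.1)), "p\\(2m\\)")
  # half-band but badly negative spectrum
  expect_error(product_filter(c(1, 0.9, 0, 0.9)), "nonnegativity")
})

test_that("filter banks round-trip through json and text serialization", {
  fb <- test_bank()
  for (ext in c("json", "txt")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_filterbank(fb, path)
    back <- read_filterbank(path)
    expect_equal(back$a0, fb$a0, tolerance = 1e-12)
    expect_equal(back$a1, fb$a1, tolerance = 1e-12)
    expect_equal(back$achieved_mssl, fb$achieved_mssl, tolerance = 1e-12)
    expect_equal(back$spec$zero_moments, fb$spec$zero_moments)
  }
})
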