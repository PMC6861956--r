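# Minimum-phase spectral factorization of the designed product filter and
# derivation of the four FIR filters of the two-channel bank.

# Synthetic division of an ascending-coefficient polynomial by (1 + z).
divide_by_1pz <- function(poly) {
  q <- numeric(length(poly) - 1L)
  q[1L] <- poly[1L]
  for (k in seq_len(length(q) - 1L) + 1L) q[k] <- poly[k] - q[k - 1L]
  q
}

# Gauss-Newton refinement of the deflated factor q so that the
# autocorrelation of conv(q, (1+z)^M) reproduces p to machine precision.
# Keeping the binomial factor exact preserves the zero moments exactly.
refine_spectral_factor <- function(q, h, p) {
  n <- length(p)
  for (iter in 1:10) {
    a <- Re(polymul(q, h))
    g <- autocorrelation(a) - p
    if (max(abs(g)) < 1e-14) break
    Ja <- matrix(0, n, n)
    for (m in 0:(n - 1L)) for (j in 1:n) {
      v <- 0
      if (j - m >= 1L) v <- v + a[j - m]
      if (j + m <= n) v <- v + a[j + m]
      Ja[m + 1L, j] <- v
    }
    K <- length(q)
    Dq <- matrix(0, n, K)
    for (j in seq_len(K)) Dq[j:(j + length(h) - 1L), j] <- h
    step <- tryCatch(qr.solve(Ja %*% Dq, -g), error = function(e) NULL)
    if (is.null(step)) break
    q <- q + step
  }
  q
}

#' Spectral factorization of a product filter into a wavelet filter bank
#'
#' Recovers the analysis low-pass filter `A0` as the minimum-phase spectral
#' factor of the nonnegative product spectrum, then derives the remaining
#' three filters by quadrature conjugation. The zero of order `2M` at
#' `z = -1` is deflated analytically before root finding, so the factor
#' carries an exact `(1+z)^M` zero-moment factor; the deflated remainder is
#' lifted by at most `psd_epsilon` plus any (solver-noise) negative dip, root
#' factored, and polished by Gauss-Newton against the designed
#' autocorrelation.
#'
#' Conventions: `sum(a0) = sqrt(2)` (DC gain `P(1) = 2`), minimum phase
#' (roots of `A0` on or inside the unit circle), `a1(n) = (-1)^n a0(N-1-n)`,
#' `b0 = rev(a0)`, `b1(n) = (-1)^(n+1) a0(n)`.
#'
#' @param pf A [product_filter()] object.
#' @param spec A [design_spec()] matching the filter (supplies `M` and
#'   `psd_epsilon`). If omitted, `M` is inferred from the order of the zero of
#'   the spectrum at `f = pi`.
#' @param achieved_mssl Optional objective value stored with the bank.
#' @return An object of class `"owfb"`: list with taps `a0`, `a1`, `b0`, `b1`,
#'   the product filter, `achieved_mssl` and the spec.
#' @export
#' @examples
#' fb <- spectral_factorize(product_filter(c(1, 0.5)), design_spec(2, 1))
#' fb$a0  # 1/sqrt(2), 1/sqrt(2)
spectral_factorize <- function(pf, spec = NULL, achieved_mssl = NULL) {
  stopifnot(inherits(pf, "product_filter"))
  p <- pf$p
  N <- pf$n_taps
  if (is.null(spec)) {
    # infer the multiplicity of the zero at z = -1 from the alternating sums
    M <- 0L
    while (M < N %/% 2L) {
      k <- M
      r <- if (k == 0L)
        p[1L] + 2 * sum((-1)^seq_len(N - 1L) * p[-1L])
      else
        sum((-1)^seq_len(N - 1L) * seq_len(N - 1L)^(2 * k) * p[-1L])
      if (abs(r) > 1e-7) break
      M <- M + 1L
    }
    if (M < 1L) stop("product filter has no zero at z = -1; not a valid ",
                     "regular half-band design", call. = FALSE)
    spec <- design_spec(N, M)
  }
  M <- spec$zero_moments
  eps <- spec$psd_epsilon

  fgrid <- seq(0, pi, length.out = 4097L)
  Pg <- product_spectrum_raw(p, fgrid)
  if (min(Pg) < -max(eps, 1e-9))
    stop("spectrum dips to ", format(min(Pg)),
         ", below -psd_epsilon; cannot factorize", call. = FALSE)

  # two-sided coefficients of P(z) z^(N-1), ascending; deflate (1+z)^(2M)
  poly <- c(rev(p[-1L]), p)
  for (i in seq_len(2L * M)) poly <- divide_by_1pz(poly)
  Kd <- N - 1L - M
  r2 <- poly  # ascending coefficients of R(z) z^Kd, R = P / (2 + 2 cos f)^M

  idx <- (0:(2L * Kd)) - Kd
  Rf <- vapply(fgrid, function(ff) Re(sum(r2 * exp(1i * ff * idx))), numeric(1))
  lift <- max(0, -min(Rf)) + eps
  r2[Kd + 1L] <- r2[Kd + 1L] + lift

  if (Kd > 0L) {
    rts <- polyroot(r2)
    inside <- rts[Mod(rts) < 1]
    if (length(inside) != Kd)
      stop("spectral factorization failed: expected ", Kd,
           " roots inside the unit circle, found ", length(inside),
           " (double roots on the circle too close to pair)", call. = FALSE)
    q <- complex(real = 1)
    for (r in inside) q <- polymul(q, c(-r, 1))
    q <- Re(q)
  } else {
    q <- 1
  }
  gam <- sqrt(sum(r2)) / abs(sum(q))  # match R(0) = |Q(1)|^2
  q <- q * gam

  h <- 1
  for (i in seq_len(M)) h <- c(0, h) + c(h, 0)  # (1 + z)^M
  q <- refine_spectral_factor(q, h, p)
  a0 <- Re(polymul(q, h))
  if (sum(a0) < 0) a0 <- -a0

  n <- seq_len(N) - 1L
  structure(list(a0 = a0,
                 a1 = (-1)^n * rev(a0),
                 b0 = rev(a0),
                 b1 = (-1)^(n + 1) * a0,
                 pf = pf,
                 achieved_mssl = achieved_mssl %||%
                   sum(mssl_weights(N) * pf$p),
                 spec = spec),
            class = "owfb")
}
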