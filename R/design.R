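#' Design specification for an orthogonal wavelet filter bank
#'
#' Bundles the knobs of the spectral-localization-optimal design problem: the
#' number of taps of the analysis low-pass filter, the number of zero moments
#' (vanishing moments) imposed at `z = -1`, the numerical floor used when the
#' designed spectrum is passed to spectral factorization, and the solver
#' tolerance of the interior-point method.
#'
#' @param filter_length Positive even integer, the number of FIR taps `N` of
#'   the analysis low-pass filter.
#' @param zero_moments Positive integer `M`, `1 <= M <= N/2`. The product
#'   filter is forced to carry a zero of order `2M` at `z = -1`, so the wavelet
#'   annihilates polynomials up to degree `M - 1`. `M = N/2` leaves no freedom
#'   and reproduces the maximally regular (Daubechies) solution.
#' @param psd_epsilon Small nonnegative lift applied to the deflated spectrum
#'   before spectral factorization, absorbing solver round-off.
#' @param solver_tolerance Positive target for the interior-point duality gap.
#'
#' @return An object of class `"owfb_spec"`.
#' @seealso [owfb()], [design_product_filter()]
#' @export
#' @examples
#' design_spec(8, 3)
design_spec <- function(filter_length = 16L, zero_moments = 4L,
                        psd_epsilon = 1e-10, solver_tolerance = 1e-9) {
  if (!is_wholenumber(filter_length) || filter_length < 2)
    stop("`filter_length` must be an integer >= 2", call. = FALSE)
  n <- as.integer(round(filter_length))
  if (n %% 2L != 0L)
    stop("`filter_length` must be even (two-channel orthogonal bank)",
         call. = FALSE)
  if (!is_wholenumber(zero_moments) || zero_moments < 1)
    stop("`zero_moments` must be a positive integer", call. = FALSE)
  m <- as.integer(round(zero_moments))
  if (m > n %/% 2L)
    stop("infeasible design: regularity constraint family requires ",
         "`zero_moments` <= filter_length / 2 (got M = ", m, ", N = ", n, ")",
         call. = FALSE)
  if (!is.numeric(psd_epsilon) || length(psd_epsilon) != 1L ||
      !is.finite(psd_epsilon) || psd_epsilon < 0)
    stop("`psd_epsilon` must be a nonnegative number", call. = FALSE)
  if (!is.numeric(solver_tolerance) || length(solver_tolerance) != 1L ||
      !is.finite(solver_tolerance) || solver_tolerance <= 0)
    stop("`solver_tolerance` must be a positive number", call. = FALSE)
  structure(list(filter_length = n, zero_moments = m,
                 psd_epsilon = psd_epsilon,
                 solver_tolerance = solver_tolerance),
            class = "owfb_spec")
}

#' @export
print.owfb_spec <- function(x, ...) {
  cat("Orthogonal wavelet filter bank design spec\n")
  cat(sprintf("  taps N = %d, zero moments M = %d\n",
              x$filter_length, x$zero_moments))
  cat(sprintf("  psd epsilon = %g, solver tolerance = %g\n",
              x$psd_epsilon, x$solver_tolerance))
  invisible(x)
}

#' Linear objective weights of the mean squared spectral localization
#'
#' The mean squared spectral localization (MSSL) of a unit-energy low-pass
#' filter, the second moment of its energy spectrum about zero frequency, is a
#' linear functional of the one-sided autocorrelation sequence `p`:
#' `sigma_f^2 = sum_m s(m) p(m)` with `s(0) = pi^2/3`, `s(m) = -4/m^2` for odd
#' `m` and `s(m) = 0` for even `m >= 2`.
#'
#' @param n_taps Positive even integer, the filter length `N`.
#' @return Numeric vector `s` of length `n_taps` (index `m = 0..N-1`).
#' @export
#' @examples
#' mssl_weights(4)  # pi^2/3, -4, 0, -4/9
mssl_weights <- function(n_taps) {
  if (!is_wholenumber(n_taps) || n_taps < 2 || round(n_taps) %% 2 != 0)
    stop("`n_taps` must be a positive even integer >= 2", call. = FALSE)
  n <- as.integer(round(n_taps))
  m <- seq_len(n - 1L)
  c(pi^2 / 3, ifelse(m %% 2L == 1L, -4 / m^2, 0))
}

# <E_m, Z> = sum_n Z[n, n+m], the m-th diagonal-sum functional as a symmetric
# matrix (KYP trace parameterization).
diag_sum_mat <- function(n, m) {
  if (m == 0L) return(diag(n))
  M <- matrix(0, n, n)
  for (k in 1:(n - m)) {
    M[k, k + m] <- M[k, k + m] + 0.5
    M[k + m, k] <- M[k + m, k] + 0.5
  }
  M
}

#' Construct a half-band product filter object
#'
#' A product filter is the autocorrelation sequence of an orthogonal low-pass
#' filter: symmetric support `-(N-1)..(N-1)` represented one-sided, with
#' `p(0) = 1` and vanishing even-indexed entries (the half-band property), and
#' a nonnegative spectrum on the unit circle.
#'
#' @param p Numeric vector, one-sided coefficients `p(0..N-1)`.
#' @param tolerance Violation allowed when validating the half-band and
#'   nonnegativity invariants.
#' @return An object of class `"product_filter"`.
#' @export
product_filter <- function(p, tolerance = 1e-8) {
  if (!is.numeric(p) || length(p) < 2L || any(!is.finite(p)))
    stop("`p` must be a finite numeric vector of length >= 2", call. = FALSE)
  n <- length(p)
  if (n %% 2L != 0L)
    stop("product filter length must be even", call. = FALSE)
  if (abs(p[1L] - 1) > tolerance)
    stop("half-band violation: p(0) must equal 1", call. = FALSE)
  # p(2), p(4), ... (1-based positions)
  if (n >= 4L && max(abs(p[seq(3L, n, by = 2L)])) > tolerance)
    stop("half-band violation: p(2m) must vanish for m >= 1", call. = FALSE)
  f <- seq(0, pi, length.out = 2049L)
  spec <- product_spectrum_raw(p, f)
  if (min(spec) < -tolerance)
    stop("nonnegativity violation: product spectrum dips to ",
         format(min(spec)), call. = FALSE)
  structure(list(p = as.numeric(p), n_taps = n), class = "product_filter")
}

#' @export
print.product_filter <- function(x, ...) {
  cat(sprintf("Half-band product filter, N = %d\n", x$n_taps))
  cat("  p:", format(signif(x$p, 6)), "\n")
  invisible(x)
}

product_spectrum_raw <- function(p, f) {
  n <- length(p)
  out <- rep(p[1L], length(f))
  for (m in seq_len(n - 1L)) out <- out + 2 * p[m + 1L] * cos(m * f)
  out
}

#' Evaluate the product-filter spectrum
#'
#' Returns `P(e^{jf}) = p(0) + 2 sum_{m>=1} p(m) cos(mf)`, the real-valued
#' frequency response of the symmetric product filter.
#'
#' @param pf A [product_filter()] object (or a plain numeric `p` vector).
#' @param frequencies Numeric vector of frequencies in radians, inside
#'   `[0, pi]`.
#' @return Numeric vector of spectrum values.
#' @export
#' @examples
#' haar <- product_filter(c(1, 0.5))
#' product_spectrum(haar, c(0, pi))  # 2 at DC, 0 at Nyquist
product_spectrum <- function(pf, frequencies) {
  p <- if (inherits(pf, "product_filter")) pf$p else as.numeric(pf)
  if (!is.numeric(frequencies) || any(!is.finite(frequencies)))
    stop("`frequencies` must be finite numeric", call. = FALSE)
  if (any(frequencies < 0 | frequencies > pi))
    stop("`frequencies` must lie in [0, pi]", call. = FALSE)
  product_spectrum_raw(p, frequencies)
}

#' Daubechies (maximal-regularity) product filter
#'
#' The unique length-`N` half-band product filter with a zero of order `N` at
#' `z = -1`, computed from the closed-form binomial spectrum
#' `P(f) = 2 cos^{2K}(f/2) sum_{k<K} C(K-1+k, k) sin^{2k}(f/2)`, `K = N/2`,
#' sampled exactly on a DFT grid. Its autocorrelation corresponds to the
#' Daubechies filter of `K` vanishing moments and serves as a feasible
#' reference point for the spectral-localization design.
#'
#' @param n_taps Even filter length `N`.
#' @return A [product_filter()] object.
#' @export
daubechies_product_filter <- function(n_taps) {
  if (!is_wholenumber(n_taps) || n_taps < 2 || round(n_taps) %% 2 != 0)
    stop("`n_taps` must be a positive even integer", call. = FALSE)
  n <- as.integer(round(n_taps))
  K <- n %/% 2L
  L <- 4L * n
  f <- 2 * pi * (0:(L - 1L)) / L
  k <- 0:(K - 1L)
  Pf <- 2 * cos(f / 2)^(2 * K) *
    vapply(f, function(ff) sum(choose(K - 1 + k, k) * sin(ff / 2)^(2 * k)),
           numeric(1))
  p <- vapply(0:(n - 1L), function(m) mean(Pf * cos(m * f)), numeric(1))
  p[1L] <- 1  # exact by construction; clean round-off
  if (n >= 4L) p[seq(3L, n, by = 2L)] <- 0
  product_filter(p)
}

#' Design the spectral-localization-optimal product filter
#'
#' Solves the semidefinite program `min s.p` over symmetric positive
#' semidefinite `Z` with the KYP trace parameterization
#' `p(m) = sum_n Z[n, n+m]`, subject to the half-band constraints
#' (`p(0) = 1`, `p(2m) = 0`) and the regularity constraints that force a zero
#' of order `2M` at `z = -1`. A zero of that order makes every feasible `Z`
#' annihilate the alternating moment vectors `((-1)^n n^k), k < M`, so the
#' solver first performs facial reduction (`Z = Q Y Q'` with `Q` spanning
#' their orthogonal complement, on which strict feasibility holds) and then
#' follows the log-det barrier central path with damped Newton steps.
#'
#' @param spec An [design_spec()] object (or arguments passed to it).
#' @param ... Used to build a spec when `spec` is a number
#'   (`design_product_filter(16, zero_moments = 4)`).
#' @return A list with components `pf` (the designed [product_filter()]),
#'   `certificate` (class `"sdp_certificate"`: the PSD matrix `Z`, the
#'   objective value, the estimated duality gap and the solver status), and
#'   `spec`.
#' @export
#' @examples
#' d <- design_product_filter(design_spec(4, 2))
#' d$pf$p  # 1, 9/16, 0, -1/16
design_product_filter <- function(spec, ...) {
  if (!inherits(spec, "owfb_spec")) spec <- design_spec(spec, ...)
  N <- spec$filter_length
  M <- spec$zero_moments
  s <- mssl_weights(N)

  # facial reduction: basis of the complement of the alternating moments
  nn <- 0:(N - 1L)
  U <- vapply(0:(M - 1L), function(k) (-1)^nn * nn^k, numeric(N))
  Q <- qr.Q(qr(U), complete = TRUE)[, (M + 1L):N, drop = FALSE]
  K <- N - M

  # half-band constraints <Q' E_{2m} Q, Y> = delta(m)
  Am <- lapply(0:(N %/% 2L - 1L),
               function(m) crossprod(Q, diag_sum_mat(N, 2L * m) %*% Q))
  b <- c(1, rep(0, N %/% 2L - 1L))
  Asv <- t(vapply(Am, svec, numeric(K * (K + 1L) / 2L)))

  Fo <- matrix(0, N, N)
  for (m in 0:(N - 1L)) Fo <- Fo + s[m + 1L] * diag_sum_mat(N, m)
  Fq <- crossprod(Q, Fo %*% Q)

  # strictly feasible start: projection of the scaled identity onto the
  # affine constraint set (PD on the reduced face for all admissible N, M)
  Yc <- diag(K) / K
  lam <- solve(tcrossprod(Asv), b - as.numeric(Asv %*% svec(Yc)))
  Y <- Yc + smat(as.numeric(crossprod(Asv, lam)), K)
  if (inherits(tryCatch(chol(Y), error = function(e) e), "error"))
    stop("interior-point initialization failed: projected start not positive ",
         "definite for N = ", N, ", M = ", M, call. = FALSE)

  nsb <- svd(Asv, nv = ncol(Asv))$v[, -seq_len(nrow(Asv)), drop = FALSE]
  d <- ncol(nsb)
  status <- "optimal"
  mu_min <- 1e-12
  if (d > 0L) {
    Bm <- lapply(seq_len(d), function(j) smat(nsb[, j], K))
    barrier_val <- function(Y, mu)
      sum(Fq * Y) - mu * determinant(Y)$modulus[1L]
    mu <- 1
    converged_last <- TRUE
    repeat {
      converged_last <- FALSE
      for (it in 1:80) {
        ch <- tryCatch(chol(Y), error = function(e) NULL)
        if (is.null(ch)) { status <- "inaccurate"; break }
        Yi <- chol2inv(ch)
        G <- Fq - mu * Yi
        g <- vapply(Bm, function(B) sum(B * G), numeric(1))
        W <- vapply(Bm, function(B) as.numeric(Yi %*% B %*% Yi),
                    numeric(K * K))
        V <- vapply(Bm, as.numeric, numeric(K * K))
        H <- mu * crossprod(V, W)
        H <- (H + t(H)) / 2
        dx <- tryCatch(solve(H + max(diag(H)) * 1e-13 * diag(d), -g),
                       error = function(e) NULL)
        if (is.null(dx)) { status <- "inaccurate"; break }
        lam2 <- -sum(g * dx)
        if (!is.finite(lam2) || lam2 < mu * 1e-10) {
          converged_last <- TRUE
          break
        }
        tstep <- 1
        f0 <- barrier_val(Y, mu)
        repeat {
          Yn <- Y
          for (j in seq_len(d)) Yn <- Yn + tstep * dx[j] * Bm[[j]]
          ok <- !inherits(tryCatch(chol(Yn), error = function(e) e), "error")
          if (ok && barrier_val(Yn, mu) <=
                f0 - 0.25 * tstep * lam2 + abs(f0) * 1e-14) break
          tstep <- tstep / 2
          if (tstep < 1e-13) { Yn <- Y; break }
        }
        Y <- Yn
        if (lam2 < mu * 1e-8) { converged_last <- TRUE; break }
      }
      if (mu <= mu_min || status == "inaccurate") break
      mu <- max(mu * 0.2, mu_min)
    }
    if (!converged_last && status == "optimal") status <- "inaccurate"
  }

  Z <- Q %*% Y %*% t(Q)
  p <- vapply(0:(N - 1L), function(m) sum(diag_sum_mat(N, m) * Z), numeric(1))
  # the even-index entries are met to solver accuracy; snap them so the
  # half-band property of the returned filter is exact (imposed, not fitted)
  p[1L] <- 1
  if (N >= 4L) p[seq(3L, N, by = 2L)] <- 0
  gap <- if (d > 0L) mu_min * K else 0
  if (status == "optimal" && gap > spec$solver_tolerance) status <- "inaccurate"
  cert <- structure(list(Z = Z, objective_value = sum(s * p),
                         duality_gap = gap, solver_status = status),
                    class = "sdp_certificate")
  list(pf = product_filter(p, tolerance = max(1e-8, spec$psd_epsilon)),
       certificate = cert, spec = spec)
}

#' @export
print.sdp_certificate <- function(x, ...) {
  cat("SDP certificate\n")
  cat(sprintf("  status: %s, objective (MSSL) = %.12g, gap <= %.3g\n",
              x$solver_status, x$objective_value, x$duality_gap))
  ev <- eigen(x$Z, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("  Z: %d x %d, eigenvalues in [%.3g, %.3g]\n",
              nrow(x$Z), ncol(x$Z), min(ev), max(ev)))
  invisible(x)
}
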