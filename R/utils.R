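# Internal numerical helpers shared by the design and transform code.

# Symmetric-matrix <-> vector isometry (off-diagonal entries scaled by sqrt(2)
# so that <A, B> = svec(A) . svec(B)).
svec <- function(M) {
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  M[upper.tri(M, diag = TRUE)] * ifelse(idx[, 1L] == idx[, 2L], 1, sqrt(2))
}

smat <- function(v, n) {
  M <- matrix(0, n, n)
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  M[upper.tri(M, diag = TRUE)] <- v / ifelse(idx[, 1L] == idx[, 2L], 1, sqrt(2))
  M + t(M) - diag(diag(M), nrow = n)
}

# Polynomial product for real/complex coefficient vectors (ascending powers).
polymul <- function(a, b) {
  out <- rep(if (is.complex(a) || is.complex(b)) 0i else 0,
             length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    rng <- i:(i + length(b) - 1L)
    out[rng] <- out[rng] + a[i] * b
  }
  out
}

# One-sided autocorrelation p(m) = sum_n a(n) a(n+m), m = 0..N-1.
autocorrelation <- function(a) {
  n <- length(a)
  vapply(0:(n - 1L), function(m) sum(a[1:(n - m)] * a[(1L + m):n]), numeric(1))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
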