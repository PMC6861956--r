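# Periodized multi-level two-channel decomposition and reconstruction.
#
# Analysis convention: circular correlation with the analysis taps followed by
# keeping the even-indexed outputs,
#   c(k) = sum_n a0(n) x(2k + n  mod L),   k = 0..L/2-1,
# and likewise d(k) with a1. Synthesis is the exact transpose (upsample by 2,
# circular convolution). Because the even-indexed autocorrelation of a0
# vanishes except at lag zero, the periodized transform is exactly orthonormal
# for every even signal length, so energy is conserved and reconstruction is
# exact to round-off.

circ_corr_ds <- function(x, h) {
  L <- length(x)
  hp <- c(h, rep(0, L - length(h)))
  cf <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(hp)), inverse = TRUE)) / L
  cf[seq(1L, L, by = 2L)]
}

circ_us_conv <- function(c, h, L) {
  cu <- numeric(L)
  cu[seq(1L, L, by = 2L)] <- c
  hp <- c(h, rep(0, L - length(h)))
  Re(stats::fft(stats::fft(cu) * stats::fft(hp), inverse = TRUE)) / L
}

#' Multi-level sub-band decomposition of an epoch
#'
#' Applies the iterated two-channel analysis bank: at each level the current
#' approximation is split by the low-pass `a0` and high-pass `a1` filters and
#' downsampled by two (periodic extension). With the default five levels the
#' result has six bands: `SB1`..`SB5` are the detail signals of levels 1..5
#' (highest to lowest frequency) and `SB6` is the level-5 approximation.
#'
#' @param epoch Numeric vector (or an `"ecg_epoch"` object), length divisible
#'   by `2^levels`.
#' @param fb An `"owfb"` filter bank.
#' @param levels Number of decomposition levels (default 5).
#' @param fs Sampling frequency in Hz used only to annotate nominal band
#'   edges; taken from the epoch when available, otherwise 128.
#' @return An object of class `"subband_set"`: list with `bands` (named list
#'   `SB1`..`SB<levels+1>`), `level_map` (band, level, `f_lo`, `f_hi` in Hz),
#'   `epoch_id` and the input length `n`.
#' @export
#' @examples
#' fb <- owfb(8, 3)
#' sbs <- subband_decompose(sin(2 * pi * (0:255) / 32), fb)
#' vapply(sbs$bands, length, integer(1))
subband_decompose <- function(epoch, fb, levels = 5L, fs = NULL) {
  stopifnot(inherits(fb, "owfb"))
  epoch_id <- NA_character_
  if (inherits(epoch, "ecg_epoch")) {
    fs <- fs %||% epoch$fs
    epoch_id <- paste(epoch$subject_id, epoch$channel, epoch$epoch_index,
                      sep = "/")
    epoch <- epoch$samples
  }
  fs <- fs %||% 128
  if (!is.numeric(epoch) || length(epoch) < 2L)
    stop("`epoch` must be a numeric vector", call. = FALSE)
  if (any(!is.finite(epoch)))
    stop("epoch contains non-finite samples", call. = FALSE)
  if (!is_wholenumber(levels) || levels < 1L)
    stop("`levels` must be a positive integer", call. = FALSE)
  levels <- as.integer(levels)
  L <- length(epoch)
  if (L < 2^levels)
    stop("epoch of length ", L, " is shorter than 2^levels = ", 2^levels,
         call. = FALSE)
  if (L %% 2^levels != 0L)
    stop("epoch length ", L, " is not divisible by 2^levels = ", 2^levels,
         "; periodized decomposition needs an even length at every level",
         call. = FALSE)

  bands <- vector("list", levels + 1L)
  x <- as.numeric(epoch)
  for (lev in seq_len(levels)) {
    bands[[lev]] <- circ_corr_ds(x, fb$a1)
    x <- circ_corr_ds(x, fb$a0)
  }
  bands[[levels + 1L]] <- x
  names(bands) <- paste0("SB", seq_len(levels + 1L))

  lev_seq <- seq_len(levels)
  level_map <- data.frame(
    band = names(bands),
    level = c(lev_seq, levels),
    type = c(rep("detail", levels), "approximation"),
    f_lo = c(fs / 2^(lev_seq + 1L), 0),
    f_hi = c(fs / 2^lev_seq, fs / 2^(levels + 1L)))

  structure(list(bands = bands, level_map = level_map,
                 epoch_id = epoch_id, n = L, levels = levels),
            class = "subband_set")
}

#' Reconstruct an epoch from its sub-band set
#'
#' Inverse of [subband_decompose()] with the same (orthonormal) bank: exact up
#' to round-off.
#'
#' @param sbs A `"subband_set"`.
#' @param fb The `"owfb"` used to decompose.
#' @return Numeric vector of length `sbs$n`.
#' @export
subband_reconstruct <- function(sbs, fb) {
  stopifnot(inherits(sbs, "subband_set"), inherits(fb, "owfb"))
  levels <- sbs$levels
  expect_len <- sbs$n / 2^levels
  if (length(sbs$bands[[levels + 1L]]) != expect_len)
    stop("band length mismatch: approximation band has ",
         length(sbs$bands[[levels + 1L]]), " coefficients, expected ",
         expect_len, call. = FALSE)
  x <- sbs$bands[[levels + 1L]]
  for (lev in rev(seq_len(levels))) {
    d <- sbs$bands[[lev]]
    if (length(d) != length(x))
      stop("band length mismatch at level ", lev, call. = FALSE)
    L <- 2L * length(x)
    x <- circ_us_conv(x, fb$a0, L) + circ_us_conv(d, fb$a1, L)
  }
  x
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("Sub-band set: %d bands from a length-%d epoch (%d levels)\n",
              length(x$bands), x$n, x$levels))
  df <- x$level_map
  df$n_coef <- vapply(x$bands, length, integer(1))
  df$energy <- vapply(x$bands, function(b) sum(b^2), numeric(1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Columnar form of a sub-band set
#'
#' @param x A `"subband_set"`.
#' @param ... Unused.
#' @return `data.frame` with columns `epoch_id`, `band`, `index`,
#'   `coefficient`, suitable for CSV export.
#' @export
as.data.frame.subband_set <- function(x, ...) {
  do.call(rbind, lapply(names(x$bands), function(b) {
    data.frame(epoch_id = x$epoch_id, band = b,
               index = seq_along(x$bands[[b]]),
               coefficient = x$bands[[b]])
  }))
}
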