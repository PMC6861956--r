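# Per-sub-band features: log-energy and signal fractal dimension.

#' Log-energy of a sub-band
#'
#' `LOGE = log(sum_n |r(n)|^2)`, the logarithm of the summed squared
#' coefficient amplitudes.
#'
#' @param band Numeric coefficient vector.
#' @param base `"natural"` (default) or `"ten"`.
#' @param band_id Optional identifier used in error messages.
#' @return Scalar log-energy.
#' @export
#' @examples
#' log_energy(c(3, 4))  # log(25)
log_energy <- function(band, base = c("natural", "ten"), band_id = NULL) {
  base <- match.arg(base)
  if (!is.numeric(band) || length(band) < 1L)
    stop("`band` must be a non-empty numeric vector", call. = FALSE)
  e <- sum(band^2)
  if (e == 0)
    stop("all-zero band", if (!is.null(band_id)) paste0(" (", band_id, ")"),
         ": log-energy undefined", call. = FALSE)
  if (base == "natural") log(e) else log10(e)
}

# Box-counting dimension of the graph of a sampled signal. The graph is
# affinely normalized into the unit square (index to [0,1], amplitude range
# to [0,1]) which makes the estimate amplitude- and scale-invariant. At
# dyadic box side m = 2^-k the graph is treated as the polyline through the
# samples (column extents include the interpolated values at column
# boundaries) and the occupied-box count of a column is its amplitude extent
# divided by the box side; summing the extents rather than flooring them to
# whole boxes removes the one-box-per-column baseline that otherwise biases
# the regression slope toward 1 at coarse scales. The scale set stops while
# columns still hold enough samples for a stable extent (>= 32 per column
# when the length permits, never above 2^-9 nor below three scales).
sfd_boxcount <- function(x) {
  n <- length(x)
  k_max <- max(5L, min(9L, floor(log2(n)) - 5L))
  ks <- 3:k_max
  if (length(ks) < 3L)
    stop("fewer than 3 usable dyadic scales for a band of length ", n,
         call. = FALSE)
  rng <- range(x)
  if (diff(rng) == 0) return(1)
  y <- (x - rng[1L]) / diff(rng)
  tpos <- (seq_len(n) - 1L) / (n - 1L)
  counts <- vapply(ks, function(k) {
    nb <- 2^k
    tb <- (1:(nb - 1L)) / nb
    yb <- stats::approx(tpos, y, xout = tb)$y
    col <- pmin(floor(tpos * nb), nb - 1L)
    allcol <- c(col, 0:(nb - 2L), 1:(nb - 1L))
    ally <- c(y, yb, yb)
    lo <- tapply(ally, allcol, min)
    hi <- tapply(ally, allcol, max)
    max(sum((hi - lo) * nb), 1)
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ I(ks * log(2))))[[2L]]
}

# Katz estimator: D = log10(L/a) / log10(d/a) with L the curve length, a the
# mean step and d the maximal distance from the first point.
sfd_katz <- function(x) {
  n <- length(x)
  steps <- sqrt(1 + diff(x)^2)
  L <- sum(steps)
  a <- L / (n - 1)
  d <- max(sqrt((seq_len(n) - 1)^2 + (x - x[1L])^2))
  log10(L / a) / log10(d / a)
}

# Higuchi estimator with dyadic delays.
sfd_higuchi <- function(x, k_max = 8L) {
  n <- length(x)
  ks <- unique(pmax(1L, round(2^(0:log2(k_max)))))
  Lk <- vapply(ks, function(k) {
    lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (floor((n - m) / k) * k) / k
    }, numeric(1))
    mean(lm, na.rm = TRUE)
  }, numeric(1))
  -stats::coef(stats::lm(log(Lk) ~ log(ks)))[[2L]]
}

#' Signal fractal dimension of a sub-band
#'
#' Estimates the fractal (self-similarity) dimension of the graph of the
#' sampled band. The default estimator counts occupied boxes `P_m` of the
#' unit-square-normalized graph over dyadic box sides `m = 2^-3 .. 2^-9`
#' (restricted by the band length) and returns the least-squares slope of
#' `log P_m` against `log(1/m)`. A smooth curve gives values near 1; rougher,
#' noise-like traces approach 2. Katz's and Higuchi's estimators are
#' available as alternatives. Results are clamped to the theoretical range
#' `[1, 2]` with a warning.
#'
#' @param band Numeric vector, length >= 64.
#' @param method `"boxcount"` (default), `"katz"` or `"higuchi"`.
#' @return Scalar dimension estimate in `[1, 2]`.
#' @export
#' @examples
#' fractal_dimension(seq(0, 1, length.out = 1024))  # ~1 for a straight line
fractal_dimension <- function(band,
                              method = c("boxcount", "katz", "higuchi")) {
  method <- match.arg(method)
  if (!is.numeric(band) || length(band) < 64L)
    stop("`band` must be numeric with at least 64 samples", call. = FALSE)
  if (any(!is.finite(band)))
    stop("`band` contains non-finite values", call. = FALSE)
  d <- switch(method,
              boxcount = sfd_boxcount(band),
              katz = sfd_katz(band),
              higuchi = sfd_higuchi(band))
  if (d < 1 - 1e-6 || d > 2 + 1e-6)
    warning("fractal dimension estimate ", format(d),
            " outside [1, 2]; clamped")
  min(max(d, 1), 2)
}

#' Sub-band feature table for a set of epochs
#'
#' Decomposes every epoch with the given bank and computes the log-energy and
#' fractal dimension of each of the `levels + 1` sub-bands, yielding the 12
#' features per epoch used by the screening index (with the default 5
#' levels). Failing epochs are skipped with a warning naming them; the
#' remaining rows are returned.
#'
#' @param epochs List of `"ecg_epoch"` objects (typically normalized with
#'   [zscore_epoch()]) or plain numeric vectors.
#' @param fb An `"owfb"` filter bank.
#' @param levels Decomposition levels (default 5).
#' @param log_base Passed to [log_energy()].
#' @param sfd_method Passed to [fractal_dimension()].
#' @return `data.frame` of class `"owfb_features"` with identifier columns
#'   (`subject_id`, `epoch_index`, `channel`, `class_label`) and feature
#'   columns `LOGE_SB1..LOGE_SB6`, `SFD_SB1..SFD_SB6`.
#' @export
feature_table <- function(epochs, fb, levels = 5L,
                          log_base = c("natural", "ten"),
                          sfd_method = c("boxcount", "katz", "higuchi")) {
  log_base <- match.arg(log_base)
  sfd_method <- match.arg(sfd_method)
  stopifnot(inherits(fb, "owfb"))
  if (inherits(epochs, "ecg_epoch") || is.numeric(epochs))
    epochs <- list(epochs)
  n_bands <- levels + 1L
  rows <- vector("list", length(epochs))
  skipped <- character(0)
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    id <- if (inherits(ep, "ecg_epoch"))
      paste(ep$subject_id, ep$channel, ep$epoch_index, sep = "/")
    else sprintf("epoch-%d", i)
    res <- tryCatch({
      sbs <- subband_decompose(ep, fb, levels = levels)
      loge <- vapply(names(sbs$bands), function(b)
        log_energy(sbs$bands[[b]], log_base, band_id = paste(id, b)),
        numeric(1))
      sfd <- vapply(sbs$bands, fractal_dimension, numeric(1),
                    method = sfd_method)
      meta <- if (inherits(ep, "ecg_epoch"))
        data.frame(subject_id = ep$subject_id, epoch_index = ep$epoch_index,
                   channel = ep$channel, class_label = ep$class_label)
      else
        data.frame(subject_id = id, epoch_index = i, channel = "CH1",
                   class_label = "unknown")
      cbind(meta,
            as.data.frame(as.list(stats::setNames(
              loge, paste0("LOGE_", names(sbs$bands))))),
            as.data.frame(as.list(stats::setNames(
              sfd, paste0("SFD_", names(sbs$bands))))))
    }, error = function(e) e)
    if (inherits(res, "error")) skipped <- c(skipped,
                                             paste0(id, " (", conditionMessage(res), ")"))
    else rows[[i]] <- res
  }
  if (length(skipped) > 0L)
    warning("skipped ", length(skipped), " epoch(s): ",
            paste(skipped, collapse = "; "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    stop("no epoch produced features", call. = FALSE)
  class(out) <- c("owfb_features", "data.frame")
  attr(out, "log_base") <- log_base
  attr(out, "sfd_method") <- sfd_method
  out
}

#' Names of the feature columns of a feature table
#' @param levels Decomposition levels.
#' @return Character vector `LOGE_SB1.. SFD_SB<levels+1>`.
#' @export
feature_names <- function(levels = 5L) {
  bands <- paste0("SB", seq_len(levels + 1L))
  c(paste0("LOGE_", bands), paste0("SFD_", bands))
}
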