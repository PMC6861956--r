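# Record containers, segmentation, normalization and the synthetic generator.

#' Construct a multi-channel ECG record
#'
#' @param channels Named list of equal-length numeric vectors (one per lead;
#'   the screening pipeline uses `CH1` = lead III, `CH2` = V3, `CH3` = V5).
#' @param fs Sampling frequency in Hz.
#' @param subject_id Identifier string.
#' @param class_label One of `"LRHT"`, `"HRHT"`, `"unknown"` (low-/high-risk
#'   hypertension).
#' @param hrht_subtype Optional event subtype for high-risk subjects:
#'   `"myocardial_infarction"`, `"stroke"` or `"syncope"`.
#' @return An object of class `"ecg_record"`.
#' @export
ecg_record <- function(channels, fs, subject_id = "anonymous",
                       class_label = c("unknown", "LRHT", "HRHT"),
                       hrht_subtype = NULL) {
  class_label <- match.arg(class_label)
  if (!is.list(channels) || length(channels) < 1L)
    stop("`channels` must be a non-empty list of numeric vectors",
         call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("CH", seq_along(channels))
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive number", call. = FALSE)
  if (!is.null(hrht_subtype))
    hrht_subtype <- match.arg(hrht_subtype,
                              c("myocardial_infarction", "stroke", "syncope"))
  structure(list(channels = channels, fs = fs, subject_id = subject_id,
                 class_label = class_label, hrht_subtype = hrht_subtype,
                 n_samples = lens[[1L]]),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record %s: %d channel(s) x %d samples @ %g Hz (%.1f min), class %s\n",
              x$subject_id, length(x$channels), x$n_samples, x$fs,
              x$n_samples / x$fs / 60, x$class_label))
  invisible(x)
}

#' Number of whole epochs in a record
#'
#' @param n_samples Record length in samples.
#' @param fs Sampling frequency in Hz.
#' @param epoch_s Epoch duration in seconds (default 300, i.e. 5 minutes).
#' @return Integer count `floor(n_samples / round(epoch_s * fs))`; trailing
#'   partial windows are discarded.
#' @export
#' @examples
#' epoch_count(999936, 128)  # 26 five-minute epochs in 2 h 10 min 12 s
epoch_count <- function(n_samples, fs, epoch_s = 300) {
  win <- round(epoch_s * fs)
  if (win < 1) stop("epoch window must contain at least one sample",
                    call. = FALSE)
  as.integer(floor(n_samples / win))
}

#' Segment a record into non-overlapping epochs
#'
#' Cuts every channel into consecutive windows of `round(epoch_s * fs)`
#' samples; a trailing partial window is discarded. Epochs are returned raw;
#' apply [zscore_epoch()] before decomposition.
#'
#' @param record An [ecg_record()].
#' @param epoch_s Epoch duration in seconds (default 300).
#' @return List of `"ecg_epoch"` objects (possibly empty, with a warning, if
#'   the record is shorter than one window). Each epoch carries `samples`,
#'   `fs`, `duration_s`, `subject_id`, `channel`, `epoch_index` and
#'   `class_label`.
#' @export
segment_record <- function(record, epoch_s = 300) {
  stopifnot(inherits(record, "ecg_record"))
  win <- round(epoch_s * record$fs)
  n_ep <- epoch_count(record$n_samples, record$fs, epoch_s)
  if (n_ep == 0L) {
    warning("record ", record$subject_id, " (", record$n_samples,
            " samples) is shorter than one epoch window of ", win,
            " samples; returning no epochs")
    return(list())
  }
  out <- vector("list", n_ep * length(record$channels))
  i <- 0L
  for (ch in names(record$channels)) {
    x <- record$channels[[ch]]
    for (k in seq_len(n_ep)) {
      i <- i + 1L
      out[[i]] <- structure(
        list(samples = x[((k - 1L) * win + 1L):(k * win)],
             fs = record$fs, duration_s = epoch_s,
             subject_id = record$subject_id, channel = ch,
             epoch_index = k, class_label = record$class_label),
        class = "ecg_epoch")
    }
  }
  out
}

#' @export
print.ecg_epoch <- function(x, ...) {
  cat(sprintf("ECG epoch %s/%s #%d: %d samples @ %g Hz, class %s\n",
              x$subject_id, x$channel, x$epoch_index, length(x$samples),
              x$fs, x$class_label))
  invisible(x)
}

#' Z-score normalize an epoch
#'
#' Centers and scales to zero mean and unit standard deviation using the
#' population convention (divide by `n`, not `n - 1`).
#'
#' @param epoch An `"ecg_epoch"` or plain numeric vector.
#' @return Same type as the input, normalized.
#' @export
#' @examples
#' zscore_epoch(c(1, 2, 3))  # -sqrt(3/2), 0, sqrt(3/2)
zscore_epoch <- function(epoch) {
  is_obj <- inherits(epoch, "ecg_epoch")
  x <- if (is_obj) epoch$samples else epoch
  if (!is.numeric(x) || length(x) < 2L)
    stop("epoch must contain at least two samples", call. = FALSE)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) {
    id <- if (is_obj)
      paste(epoch$subject_id, epoch$channel, epoch$epoch_index, sep = "/")
    else "<numeric epoch>"
    stop("zero-variance (flatline) epoch: ", id, call. = FALSE)
  }
  z <- (x - mu) / sdev
  if (is_obj) { epoch$samples <- z; epoch } else z
}

#' Synthesize a multi-channel ECG-like record
#'
#' Deterministic fixture generator: each channel is a circular train of
#' QRS-like complexes (Gaussian-derivative pulses) at the requested heart
#' rate, scaled per channel, plus stationary AR(1) colored noise. When the
#' beat period in samples is an integer and `noise_sd = 0` the signal is
#' exactly periodic. The generator emulates the gross morphology and
#' amplitude statistics of Holter ECG for plumbing and property tests only;
#' it makes no claim of reproducing class-discriminating (hypertensive)
#' morphology, so class labels are carried as metadata, not encoded in the
#' waveform.
#'
#' @param class_label Stored label, one of `"unknown"`, `"LRHT"`, `"HRHT"`.
#' @param fs Sampling frequency in Hz (default 128).
#' @param duration_s Record duration in seconds (>= 300).
#' @param heart_rate_bpm Beats per minute (default 72).
#' @param noise_sd Stationary standard deviation of the AR(1) noise relative
#'   to the unit QRS amplitude (default 0.1).
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @param subject_id Identifier.
#' @param hrht_subtype Optional event subtype, stored as metadata.
#' @return An [ecg_record()] with channels `CH1`, `CH2`, `CH3`.
#' @export
synthesize_ecg_record <- function(class_label = c("unknown", "LRHT", "HRHT"),
                                  fs = 128, duration_s = 7812,
                                  heart_rate_bpm = 72, noise_sd = 0.1,
                                  seed = 1L, subject_id = NULL,
                                  hrht_subtype = NULL) {
  class_label <- match.arg(class_label)
  if (!is.numeric(duration_s) || duration_s < 300)
    stop("`duration_s` must be at least 300 seconds", call. = FALSE)
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop("`heart_rate_bpm` must be positive", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (!is_wholenumber(seed)) stop("`seed` must be an integer", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n <- round(duration_s * fs)
  period <- 60 / heart_rate_bpm * fs
  # QRS-like template: derivative of a Gaussian, ~80 ms wide
  half <- round(0.08 * fs)
  tt <- seq(-half, half)
  sigma <- 0.02 * fs
  template <- -tt / sigma * exp(0.5 - tt^2 / (2 * sigma^2))

  beat_starts <- round(seq(0, n - 1, by = period))
  base <- numeric(n)
  for (b in beat_starts) {
    idx <- ((b + tt) %% n) + 1L
    base[idx] <- base[idx] + template
  }

  ch_gain <- c(CH1 = 0.7, CH2 = 1.0, CH3 = 1.2)
  channels <- lapply(ch_gain, function(g) {
    x <- g * base
    if (noise_sd > 0) {
      phi <- 0.9
      eps <- stats::rnorm(n, sd = noise_sd * sqrt(1 - phi^2))
      x <- x + as.numeric(stats::filter(eps, phi, method = "recursive"))
    }
    x
  })
  if (is.null(subject_id))
    subject_id <- sprintf("synth-%s-%d", tolower(class_label), seed)
  ecg_record(channels, fs, subject_id, class_label, hrht_subtype)
}
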