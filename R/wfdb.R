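# Minimal WFDB (PhysioNet) record reader/writer: header parsing plus the two
# signal formats used by Holter archives of interest, format 16 (little-endian
# 16-bit two's complement) and format 80 (8-bit offset binary), multiplexed
# sample-by-sample in a single .dat file.

parse_wfdb_gain <- function(field) {
  # "gain(baseline)/units", all parts optional; defaults per WFDB spec
  gain <- 200
  baseline <- 0
  units <- NA_character_
  if (!is.na(field) && nzchar(field)) {
    main <- strsplit(field, "/", fixed = TRUE)[[1L]]
    if (length(main) > 1L) units <- main[2L]
    g <- main[1L]
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", g))
      g <- sub("\\(.*", "", g)
    }
    if (nzchar(g)) gain <- as.numeric(g)
    if (gain == 0) gain <- 200
  }
  list(gain = gain, baseline = baseline, units = units)
}

#' Read a WFDB record
#'
#' Parses a PhysioNet-style header (`.hea`) and loads the multiplexed signal
#' file. Supported signal formats: 16 (16-bit little-endian) and 80 (8-bit
#' offset binary, the format of 8-bit Holter archives). Samples are converted
#' to physical units via `(adc - baseline) / gain`.
#'
#' @param path Path to the `.hea` file, or the record name without extension.
#' @param class_label Optional class label to attach (`"LRHT"`, `"HRHT"`,
#'   `"unknown"`).
#' @return An [ecg_record()] with one named channel per signal (falling back
#'   to `CH1..CHk` when the header has no description fields).
#' @export
read_wfdb <- function(path, class_label = "unknown") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing WFDB header: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("corrupt WFDB header (empty): ", hea,
                               call. = FALSE)
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 3L) stop("corrupt WFDB header record line: ", hea,
                             call. = FALSE)
  name <- rec[1L]
  nsig <- as.integer(rec[2L])
  fs <- as.numeric(strsplit(rec[3L], "/", fixed = TRUE)[[1L]][1L])
  nsamp <- if (length(rec) >= 4L) as.numeric(rec[4L]) else NA_real_
  if (is.na(nsig) || nsig < 1L)
    stop("WFDB record declares no signals: ", hea, call. = FALSE)
  if (length(lines) < 1L + nsig)
    stop("WFDB header declares ", nsig, " signals but lists fewer: ", hea,
         call. = FALSE)

  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    fields <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*|:.*|\\+.*", "", fields[2L]))
    g <- parse_wfdb_gain(if (length(fields) >= 3L) fields[3L] else "")
    desc <- if (length(fields) >= 9L)
      paste(fields[9:length(fields)], collapse = " ") else NA_character_
    list(file = fields[1L], fmt = fmt, gain = g$gain, baseline = g$baseline,
         desc = desc)
  })
  fmts <- unique(vapply(sig, `[[`, integer(1), "fmt"))
  files <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(fmts) != 1L || length(files) != 1L)
    stop("only single-file, single-format WFDB records are supported",
         call. = FALSE)
  if (!fmts %in% c(16L, 80L))
    stop("unsupported WFDB signal format ", fmts,
         " (formats 16 and 80 are supported)", call. = FALSE)

  dat <- file.path(dirname(hea), files)
  if (!file.exists(dat)) stop("missing WFDB signal file: ", dat,
                              call. = FALSE)
  sz <- file.info(dat)$size
  adc <- if (fmts == 16L)
    readBin(dat, "integer", n = sz / 2, size = 2L, signed = TRUE,
            endian = "little")
  else
    readBin(dat, "integer", n = sz, size = 1L, signed = FALSE) - 128L
  n_per <- length(adc) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) n_per <- min(n_per, nsamp)
  adc <- matrix(adc[seq_len(n_per * nsig)], nrow = nsig)

  channels <- lapply(seq_len(nsig), function(i)
    (adc[i, ] - sig[[i]]$baseline) / sig[[i]]$gain)
  nm <- vapply(sig, `[[`, character(1), "desc")
  names(channels) <- ifelse(is.na(nm) | !nzchar(nm),
                            paste0("CH", seq_len(nsig)), nm)
  ecg_record(channels, fs, subject_id = name, class_label = class_label)
}

#' Write an ECG record in WFDB format
#'
#' Companion writer used to build on-the-fly fixtures and to export records
#' for WFDB-consuming tools. Quantizes each channel with the given gain.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory.
#' @param name Record name (defaults to the subject id).
#' @param format 16 (default) or 80.
#' @param gain ADC units per physical unit (default 200; clipped to the 8-bit
#'   range for format 80).
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, name = NULL, format = 16L, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!format %in% c(16L, 80L)) stop("format must be 16 or 80", call. = FALSE)
  name <- name %||% record$subject_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nsig <- length(record$channels)
  adc <- vapply(record$channels, function(x) round(x * gain),
                numeric(record$n_samples))
  lim <- if (format == 80L) 127 else 32767
  adc <- pmin(pmax(t(adc), -lim), lim)  # nsig x n, interleave by column
  datfile <- paste0(name, ".dat")
  con <- file(file.path(dir, datfile), "wb")
  if (format == 16L) {
    writeBin(as.integer(adc), con, size = 2L, endian = "little")
  } else {
    writeBin(as.raw(as.integer(adc) + 128L), con)
  }
  close(con)
  hdr <- c(sprintf("%s %d %g %d", name, nsig, record$fs, record$n_samples),
           sprintf("%s %d %g(0)/mV 0 0 0 0 0 %s", datfile, format, gain,
                   names(record$channels)))
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(hdr, hea)
  invisible(hea)
}
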