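# Plain-text serialization of designed filter banks.

#' Write a filter bank to disk
#'
#' Two formats: `"json"` (all four filters, the product filter, spec and
#' achieved MSSL) and `"txt"` (header lines `# n_taps`, `# zero_moments`,
#' `# achieved_mssl`, then one `a0` tap per line).
#'
#' @param fb An `"owfb"` object.
#' @param path Output file.
#' @param format `"json"` or `"txt"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_filterbank <- function(fb, path, format = c("auto", "json", "txt")) {
  stopifnot(inherits(fb, "owfb"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "txt"
  if (format == "json") {
    obj <- list(n_taps = fb$spec$filter_length,
                zero_moments = fb$spec$zero_moments,
                achieved_mssl = fb$achieved_mssl,
                a0 = fb$a0, a1 = fb$a1, b0 = fb$b0, b1 = fb$b1,
                product_filter = fb$pf$p)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# n_taps %d", fb$spec$filter_length),
                 sprintf("# zero_moments %d", fb$spec$zero_moments),
                 sprintf("# achieved_mssl %.17g", fb$achieved_mssl),
                 sprintf("%.17g", fb$a0)), con)
  }
  invisible(path)
}

#' Read a filter bank written by [write_filterbank()]
#'
#' @param path File path (json or txt).
#' @return An `"owfb"` object. For the txt format the remaining filters are
#'   rebuilt from `a0` by quadrature conjugation.
#' @export
read_filterbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    spec <- design_spec(obj$n_taps, obj$zero_moments)
    n <- seq_len(obj$n_taps) - 1L
    a0 <- as.numeric(obj$a0)
    structure(list(a0 = a0,
                   a1 = as.numeric(obj$a1), b0 = as.numeric(obj$b0),
                   b1 = as.numeric(obj$b1),
                   pf = product_filter(as.numeric(obj$product_filter),
                                       tolerance = 1e-6),
                   achieved_mssl = obj$achieved_mssl, spec = spec),
              class = "owfb")
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    get <- function(key) {
      ln <- hdr[grepl(paste0("# ", key), hdr, fixed = TRUE)][1L]
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]][3L])
    }
    a0 <- as.numeric(lines[!startsWith(lines, "#") & nzchar(trimws(lines))])
    N <- length(a0)
    if (N != get("n_taps")) stop("tap count does not match header",
                                 call. = FALSE)
    spec <- design_spec(N, get("zero_moments"))
    n <- 0:(N - 1L)
    structure(list(a0 = a0,
                   a1 = (-1)^n * rev(a0),
                   b0 = rev(a0),
                   b1 = (-1)^(n + 1) * a0,
                   pf = product_filter(autocorrelation(a0), tolerance = 1e-6),
                   achieved_mssl = get("achieved_mssl"), spec = spec),
              class = "owfb")
  }
}
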