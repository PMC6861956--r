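# Shared test fixtures, generated in code.

# Fractional-Brownian-like trace by midpoint displacement. The graph of such
# a trace has box-counting dimension 2 - H in theory, which makes it the
# oracle for the fractal-dimension estimator.
fbm_midpoint <- function(n, hurst, seed) {
  levels <- ceiling(log2(n - 1))
  set.seed(seed)
  x <- c(0, rnorm(1))
  sd_step <- 1
  for (lev in seq_len(levels)) {
    sd_step <- sd_step / 2^hurst
    mid <- (x[-length(x)] + x[-1]) / 2 + rnorm(length(x) - 1, sd = sd_step)
    y <- numeric(2 * length(x) - 1)
    y[seq(1, length(y), by = 2)] <- x
    y[seq(2, length(y), by = 2)] <- mid
    x <- y
  }
  x[seq_len(n)]
}

rand_epoch <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}

# A small bank reused across tests (designed once per test file load).
test_bank <- local({
  fb <- NULL
  function() {
    if (is.null(fb)) fb <<- owfb(8, 3)
    fb
  }
})

# Feature table with both class labels from short synthetic records.
two_class_features <- function(fb, duration_s = 600, seed = 11) {
  recs <- list(
    synthesize_ecg_record("LRHT", duration_s = duration_s, seed = seed),
    synthesize_ecg_record("HRHT", duration_s = duration_s, seed = seed + 1))
  eps <- lapply(unlist(lapply(recs, segment_record), recursive = FALSE),
                zscore_epoch)
  feature_table(eps, fb)
}
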