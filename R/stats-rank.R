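# Two-sample t ranking of sub-band features.

#' Rank features by two-sample Student's t-test
#'
#' For every feature column, computes the two-sided two-sample t statistic
#' between the low-risk (`LRHT`) and high-risk (`HRHT`) rows — pooled
#' variance by default ("Student's" test), Welch's unequal-variance form by
#' option — and ranks the features by decreasing absolute t.
#'
#' @param features An `"owfb_features"` table (or data.frame with a
#'   `class_label` column and feature columns).
#' @param welch If `TRUE` use Welch's t instead of pooled-variance Student's.
#' @param columns Feature columns to rank (default: all `LOGE_*`/`SFD_*`).
#' @return `data.frame` of class `"owfb_ranks"` with columns `rank`,
#'   `feature`, `t_value`, `p_value`, sorted by `|t|` descending.
#' @export
rank_features_ttest <- function(features, welch = FALSE, columns = NULL) {
  if (!is.data.frame(features) || is.null(features$class_label))
    stop("`features` must be a feature table with a class_label column",
         call. = FALSE)
  g1 <- features$class_label == "LRHT"
  g2 <- features$class_label == "HRHT"
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("need at least two rows of each class (LRHT and HRHT); got ",
         sum(g1), " and ", sum(g2), call. = FALSE)
  if (is.null(columns))
    columns <- grep("^(LOGE|SFD)_", names(features), value = TRUE)
  if (length(columns) == 0L) stop("no feature columns found", call. = FALSE)

  res <- lapply(columns, function(cn) {
    x <- features[[cn]][g1]
    y <- features[[cn]][g2]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warning("zero pooled variance for ", cn, "; t reported as +/-Inf")
      tv <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
      pv <- if (tv == 0) 1 else 0
    } else {
      ht <- stats::t.test(x, y, var.equal = !welch)
      tv <- unname(ht$statistic)
      pv <- ht$p.value
    }
    data.frame(feature = cn, t_value = tv, p_value = pv)
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$t_value)), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("owfb_ranks", "data.frame")
  out
}

#' Default feature subset of the hypertension diagnosis index
#'
#' The six sub-band features entering the index: `LOGE_SB2`, `LOGE_SB3`,
#' `SFD_SB6`, `SFD_SB2`, `SFD_SB3`, `SFD_SB4`.
#'
#' @return Character vector of length 6.
#' @export
hdi_feature_names <- function() {
  c("LOGE_SB2", "LOGE_SB3", "SFD_SB6", "SFD_SB2", "SFD_SB3", "SFD_SB4")
}

#' Select features from a rank table
#'
#' @param rank_table An `"owfb_ranks"` table.
#' @param names Feature names to select; defaults to the index subset
#'   [hdi_feature_names()].
#' @param top Alternatively, select the `top` highest-ranked features.
#' @return Character vector of feature names (in rank order when `top` is
#'   used).
#' @export
select_features <- function(rank_table, names = hdi_feature_names(),
                            top = NULL) {
  stopifnot(is.data.frame(rank_table), !is.null(rank_table$feature))
  if (!is.null(top)) {
    if (!is_wholenumber(top) || top < 1 || top > nrow(rank_table))
      stop("`top` must be between 1 and the number of ranked features",
           call. = FALSE)
    return(rank_table$feature[order(rank_table$rank)][seq_len(top)])
  }
  if (length(names) == 0L) stop("empty feature selection", call. = FALSE)
  missing <- setdiff(names, rank_table$feature)
  if (length(missing) > 0L)
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  names
}
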