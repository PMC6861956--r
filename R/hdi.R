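# The hypertension diagnosis index: a fixed linear combination of six
# sub-band features, plus range- or threshold-based classification.

#' Compute the hypertension diagnosis index
#'
#' `HDI = 6 - (3 LOGE_SB2 + 4 LOGE_SB3 + SFD_SB6)
#'          - 15 (SFD_SB2 + SFD_SB3 + SFD_SB4)`,
#' evaluated exactly as printed in its source. The index is affine in each
#' feature with coefficients (-3, -4, -1, -15, -15, -15). A `coefficients`
#' argument allows substituting a user-supplied linear index over the same or
#' other features without code changes.
#'
#' @param loge_sb2,loge_sb3,sfd_sb6,sfd_sb2,sfd_sb3,sfd_sb4 The six feature
#'   values. Alternatively pass a single named list/vector or a feature-table
#'   row as `loge_sb2`.
#' @param coefficients Optional named numeric vector `c(intercept = ...,
#'   <feature> = <coef>, ...)` replacing the default index.
#' @return Scalar index value (or vector, if vectors are supplied).
#' @export
#' @examples
#' compute_hdi(0, 0, 0, 0, 0, 0)  # 6
compute_hdi <- function(loge_sb2, loge_sb3 = NULL, sfd_sb6 = NULL,
                        sfd_sb2 = NULL, sfd_sb3 = NULL, sfd_sb4 = NULL,
                        coefficients = NULL) {
  if (is.null(loge_sb3) && (is.list(loge_sb2) || !is.null(names(loge_sb2)))) {
    f <- loge_sb2
    pick <- function(nm) {
      v <- f[[nm]]
      if (is.null(v)) stop("missing feature ", nm, call. = FALSE)
      as.numeric(v)
    }
    loge_sb2 <- pick("LOGE_SB2"); loge_sb3 <- pick("LOGE_SB3")
    sfd_sb6 <- pick("SFD_SB6"); sfd_sb2 <- pick("SFD_SB2")
    sfd_sb3 <- pick("SFD_SB3"); sfd_sb4 <- pick("SFD_SB4")
  }
  vals <- list(LOGE_SB2 = loge_sb2, LOGE_SB3 = loge_sb3, SFD_SB6 = sfd_sb6,
               SFD_SB2 = sfd_sb2, SFD_SB3 = sfd_sb3, SFD_SB4 = sfd_sb4)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-finite value for feature ", nm, call. = FALSE)
  }
  if (!is.null(coefficients)) {
    ic <- if ("intercept" %in% names(coefficients))
      coefficients[["intercept"]] else 0
    out <- rep(ic, length(vals[[1L]]))
    for (nm in setdiff(names(coefficients), "intercept")) {
      if (is.null(vals[[nm]]))
        stop("coefficient for unknown feature ", nm, call. = FALSE)
      out <- out + coefficients[[nm]] * vals[[nm]]
    }
    return(out)
  }
  6 - (3 * vals$LOGE_SB2 + 4 * vals$LOGE_SB3 + vals$SFD_SB6) -
    15 * (vals$SFD_SB2 + vals$SFD_SB3 + vals$SFD_SB4)
}

#' Classify an index value against class ranges or a threshold
#'
#' With ranges (the default reported operating ranges, low-risk
#' `[1.501, 2.355]` and high-risk `[2.774, 6.084]`): a value inside a range
#' is assigned that class, anything else is `"indeterminate"`. With a scalar
#' `threshold`, a two-way split (`< threshold` is low-risk) is applied
#' instead.
#'
#' @param hdi_value Numeric vector of index values.
#' @param ranges List with components `lrht` and `hrht`, each `c(lo, hi)`.
#'   Must be disjoint.
#' @param threshold Optional scalar overriding range classification.
#' @return Character vector in `{"LRHT", "HRHT", "indeterminate"}`.
#' @export
#' @examples
#' classify_hdi(c(2.0, 3.5, 2.5))
classify_hdi <- function(hdi_value,
                         ranges = list(lrht = c(1.501, 2.355),
                                       hrht = c(2.774, 6.084)),
                         threshold = NULL) {
  if (!is.numeric(hdi_value) || any(!is.finite(hdi_value)))
    stop("`hdi_value` must be finite numeric", call. = FALSE)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("`threshold` must be a single number", call. = FALSE)
    return(ifelse(hdi_value < threshold, "LRHT", "HRHT"))
  }
  lr <- sort(as.numeric(ranges$lrht))
  hr <- sort(as.numeric(ranges$hrht))
  if (length(lr) != 2L || length(hr) != 2L || any(!is.finite(c(lr, hr))))
    stop("`ranges` must give finite c(lo, hi) for lrht and hrht",
         call. = FALSE)
  if (max(min(lr[2L], hr[2L]) - max(lr[1L], hr[1L]), 0) > 0)
    stop("overlapping class ranges are not allowed", call. = FALSE)
  ifelse(hdi_value >= lr[1L] & hdi_value <= lr[2L], "LRHT",
         ifelse(hdi_value >= hr[1L] & hdi_value <= hr[2L], "HRHT",
                "indeterminate"))
}

#' Index table for a feature table
#'
#' Computes the index and its classification for every row of a feature
#' table (optionally restricted to one channel).
#'
#' @param features An `"owfb_features"` table.
#' @param channel Optional channel filter (the reported headline channel is
#'   `CH3`, lead V5).
#' @param ... Passed to [classify_hdi()] (`ranges`, `threshold`) and
#'   [compute_hdi()] (`coefficients`).
#' @return `data.frame` with identifier columns, `hdi` and `predicted_class`.
#' @export
hdi_table <- function(features, channel = NULL, ...) {
  stopifnot(is.data.frame(features))
  if (!is.null(channel)) {
    features <- features[features$channel == channel, , drop = FALSE]
    if (nrow(features) == 0L)
      stop("no rows for channel ", channel, call. = FALSE)
  }
  dots <- list(...)
  hdi <- compute_hdi(features,
                     coefficients = dots$coefficients)
  cls <- do.call(classify_hdi,
                 c(list(hdi_value = hdi),
                   dots[intersect(names(dots), c("ranges", "threshold"))]))
  cbind(features[, intersect(c("subject_id", "epoch_index", "channel",
                               "class_label"), names(features)),
                 drop = FALSE],
        data.frame(hdi = hdi, predicted_class = cls))
}
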