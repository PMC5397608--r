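# Classifier evaluation: class labels from the Tm - Tagg gap, ROC/AUC by
# pair counting, Matthews correlation, Pearson correlation.

#' Label antibodies by their melting / aggregation-onset gap
#'
#' An antibody whose aggregation onset precedes global unfolding by more
#' than `gap_cutoff` degrees (strictly) is labeled aggregation-prone
#' (class 1); others are class 0. Explicit overrides win over the gap rule,
#' which accommodates antibodies that aggregate before any measurement is
#' possible.
#'
#' @param records Data frame with columns `antibody` and either `gap`
#'   (`t_m - t_agg`, degrees C) or both `t_m` and `t_agg`.
#' @param gap_cutoff Gap cutoff in degrees C, default 5.
#' @param forced Named integer vector of label overrides, e.g.
#'   `c(mAb7 = 1)`.
#' @return The records with columns `gap` and `label` filled in.
#' @export
label_records <- function(records, gap_cutoff = 5.0, forced = NULL) {
  df <- as.data.frame(records)
  if (!"gap" %in% names(df)) {
    if (!all(c("t_m", "t_agg") %in% names(df)))
      stop("records need a 'gap' column or both 't_m' and 't_agg'")
    df$gap <- df$t_m - df$t_agg
  }
  df$label <- ifelse(is.na(df$gap), NA_integer_,
                     as.integer(df$gap > gap_cutoff))
  if (!is.null(forced)) {
    hit <- match(names(forced), df$antibody)
    if (anyNA(hit))
      stop("forced label for unknown antibody: ",
           paste(names(forced)[is.na(hit)], collapse = ", "))
    df$label[hit] <- as.integer(forced)
  }
  if (anyNA(df$label)) {
    bad <- df$antibody[is.na(df$label)]
    stop("no gap and no forced label for: ", paste(bad, collapse = ", "))
  }
  df
}

#' Receiver operating characteristic of a score
#'
#' Thresholds are placed at every distinct score (prediction rule:
#' score >= threshold is positive), plus a threshold above all scores. The
#' area under the curve is computed by the Mann-Whitney pair-counting
#' identity -- the fraction of (positive, negative) pairs ranked correctly,
#' ties counting one half -- which makes the tie convention explicit.
#'
#' @param scores Numeric scores (higher = more aggregation-prone).
#' @param labels 0/1 class labels, same length.
#' @return A list of class `roc_curve`: `points` (data frame `threshold`,
#'   `tpr`, `fpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("need at least one positive and one negative")
  thr <- c(sort(unique(scores), decreasing = TRUE), Inf)
  thr <- sort(thr, decreasing = TRUE)
  pts <- data.frame(threshold = thr,
                    tpr = vapply(thr, function(t)
                      sum(scores >= t & labels == 1L) / np, numeric(1)),
                    fpr = vapply(thr, function(t)
                      sum(scores >= t & labels == 0L) / nn, numeric(1)))
  r <- rank(scores)                        # midranks handle ties
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<ROC>", nrow(x$points), "thresholds, AUC =",
      format(round(x$auc, 4)), "\n")
  invisible(x)
}

#' Matthews correlation coefficient at a score threshold
#'
#' Predicts positive for `score >= threshold` and computes the standard MCC
#' of the resulting confusion table; if any marginal of the table is zero
#' the coefficient is defined as 0.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 class labels.
#' @param threshold Decision threshold.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("need both classes present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
}

#' Pearson product-moment correlation
#'
#' Thin, guarded wrapper around [stats::cor()] used for score-versus-gap
#' correlation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  stats::cor(x, y)
}
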