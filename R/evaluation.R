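#' ROC curve and AUC for a scoring function
#'
#' Threshold sweep over descending scores (a molecule is called active at
#' threshold t when score >= t). The AUC is computed by the rank
#' (Mann-Whitney) statistic with tied pairs contributing 1/2, which equals
#' the trapezoidal area under the (FPR, TPR) curve.
#'
#' @param scores Numeric scores (higher = more likely active).
#' @param labels Binary labels (logical, or 0/1) marking actives.
#' @return An object of class `"roc_result"`: `thresholds` (descending),
#'   `tpr`, `fpr` (curve points starting at (0,0) and ending at (1,1)),
#'   and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")

  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative TP/FP at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d actives vs %d decoys, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
#' @method plot roc_result
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", lwd = 2,
                 xlab = "FPR (1 - specificity)", ylab = "TPR (sensitivity)",
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Empirical cumulative score distribution
#'
#' @param scores Non-empty numeric vector.
#' @return Data frame with `score` (sorted) and `fraction` (cumulative,
#'   ending at 1); the median is the score where `fraction` first reaches
#'   0.5.
#' @export
cumulative_curve <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no scores")
  s <- sort(scores)
  data.frame(score = s, fraction = seq_along(s) / length(s))
}

#' Empirical quantile cutoffs
#'
#' Linear interpolation between order statistics (type 7).
#'
#' @param scores Non-empty numeric vector.
#' @param probs Probabilities, default quartiles and median.
#' @return Named numeric vector of cutoffs.
#' @export
quantile_cutoffs <- function(scores, probs = c(0.25, 0.5, 0.75)) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no scores")
  stats::quantile(scores, probs = probs, type = 7)
}

#' Optimal score cutoff by Youden's J
#'
#' Scans the observed scores as candidate thresholds (active called at
#' score >= t) and returns the one maximising J = TPR - FPR; ties are
#' broken toward the smaller threshold. Any hard cutoff turns the
#' continuous score back into a qualitative filter, so this utility is
#' discouraged for qualitative use — rank and select instead.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `J`, `tpr`, `fpr` and a `note` flagging
#'   the caveat above.
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  thr <- sort(unique(scores))
  stats <- vapply(thr, function(t) {
    pred <- scores >= t
    c(tpr = sum(pred & labels) / n_pos, fpr = sum(pred & !labels) / n_neg)
  }, numeric(2))
  j <- stats["tpr", ] - stats["fpr", ]
  best <- which(j == max(j))[1L]  # thr ascending -> first max is smallest
  list(threshold = thr[best], J = j[best], tpr = stats["tpr", best],
       fpr = stats["fpr", best],
       note = "discouraged for qualitative use; prefer ranking by score")
}
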