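# Pixelwise diagnostic evaluation against the registered pathology mask:
# confusion counts, TPR/FPR, ROC curves per structuring element, AUC, and
# best/second-best threshold selection by TPR - FPR.

#' Evaluable region: pixels where both classifications carry tissue
#'
#' Pixels where the terahertz and pathology supports do not match spatially
#' are "not applicable" and excluded from all counts.
#'
#' @param pred_support,truth_support logical masks of identical shape.
#' @return logical mask (elementwise AND).
#' @export
evaluable_mask <- function(pred_support, truth_support) {
  if (!identical(dim(pred_support), dim(truth_support)))
    stop_thz("support shapes differ", "thz_shape_error")
  pred_support & truth_support
}

#' Confusion counts over the evaluable region
#'
#' The pathology mask defines the positives: on disagreement the
#' pathologist classification prevails, predictions never reweight counts.
#'
#' @param pred predicted malignant mask (terahertz side).
#' @param truth pathology malignant mask.
#' @param evaluable logical mask of countable pixels (default: everywhere).
#' @return an object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, evaluable = NULL) {
  if (is.null(evaluable)) evaluable <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!identical(dim(pred), dim(truth)) ||
      !identical(dim(pred), dim(evaluable)))
    stop_thz("mask shapes differ", "thz_shape_error")
  if (!any(evaluable))
    stop_thz("empty evaluable region (\"not applicable\" everywhere)",
             "thz_empty_region")
  p <- pred[evaluable]; t <- truth[evaluable]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' True positive rate (sensitivity)
#'
#' TPR = TP / (TP + FN).
#'
#' @param counts a `confusion_counts`.
#' @return sensitivity in [0, 1].
#' @export
tpr <- function(counts) {
  if (counts$tp + counts$fn == 0)
    stop_thz("TPR undefined: no positive pixels", "thz_undefined_rate")
  counts$tp / (counts$tp + counts$fn)
}

#' False positive rate (1 - specificity)
#'
#' FPR = FP / (FP + TN).
#'
#' @param counts a `confusion_counts`.
#' @return false positive rate in [0, 1].
#' @export
fpr <- function(counts) {
  if (counts$fp + counts$tn == 0)
    stop_thz("FPR undefined: no negative pixels", "thz_undefined_rate")
  counts$fp / (counts$fp + counts$tn)
}

#' ROC curve of a thresholded (and dilated) index-map classifier
#'
#' For each threshold: binarize the map, apply one constrained dilation
#' pass with the given structuring element, count the confusion over the
#' evaluable region, and record (TPR, FPR, TPR - FPR).
#'
#' @param map an `index_map`.
#' @param truth pathology malignant mask on the terahertz grid.
#' @param evaluable logical mask of countable pixels (default:
#'   `map$support & truth-support`, i.e. everywhere both carry tissue —
#'   here taken as `map$support`).
#' @param se a `structuring_element` (its rank labels the curve).
#' @param thresholds refractive-index thresholds; default 1.5..3 step 0.1.
#' @return a data.frame of class `roc_curve` with columns threshold, tp,
#'   fp, tn, fn, tpr, fpr, youden; attribute `classifier_rank`.
#' @export
roc_curve <- function(map, truth, evaluable = NULL, se = make_structuring_element(0),
                      thresholds = seq(1.5, 3, by = 0.1)) {
  if (!length(thresholds))
    stop_thz("thresholds must be non-empty", "thz_domain_error")
  if (is.null(evaluable)) evaluable <- map$support
  rows <- lapply(thresholds, function(t) {
    pred <- dilate_mask(threshold_map(map, t), se, support = map$support)
    cc <- confusion_counts(pred, truth, evaluable)
    data.frame(threshold = t, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               tpr = tpr(cc), fpr = fpr(cc))
  })
  out <- do.call(rbind, rows)
  out$youden <- out$tpr - out$fpr
  out <- out[order(out$threshold), ]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  attr(out, "classifier_rank") <- se$rank
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over FPR after sorting the points by (FPR, TPR)
#' and anchoring the endpoints (0, 0) and (1, 1). Dilated curves need not
#' be monotone in the threshold, hence the internal sort.
#'
#' @param curve a `roc_curve` (or data.frame with `tpr`, `fpr`), >= 2 points.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(curve) {
  if (nrow(curve) < 2)
    stop_thz("AUC needs at least two curve points", "thz_domain_error")
  x <- c(0, curve$fpr, 1)
  y <- c(0, curve$tpr, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Best thresholds by the TPR - FPR criterion
#'
#' Top-k curve points by descending TPR - FPR; ties broken by higher
#' specificity (lower FPR), then by lower threshold.
#'
#' @param curve a `roc_curve`.
#' @param k number of thresholds to return (default 2: best and second
#'   best, as tabulated per classifier).
#' @return data.frame with threshold, tpr, fpr, youden, sensitivity_pct,
#'   specificity_pct.
#' @export
best_thresholds <- function(curve, k = 2) {
  if (k < 1) stop_thz("k must be >= 1", "thz_domain_error")
  if (k > nrow(curve)) {
    message(sprintf("best_thresholds: k=%d exceeds curve length %d; returning all",
                    k, nrow(curve)))
    k <- nrow(curve)
  }
  o <- order(-curve$youden, curve$fpr, curve$threshold)
  top <- curve[o[seq_len(k)], c("threshold", "tpr", "fpr", "youden")]
  top$sensitivity_pct <- 100 * top$tpr
  top$specificity_pct <- 100 * (1 - top$fpr)
  rownames(top) <- NULL
  top
}
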