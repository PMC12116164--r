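#' Confusion matrix for paired label masks
#'
#' @param pred_masks,true_masks A matrix, or list of matrices, of integer
#'   labels in `[0, n_classes)`. Pairs must have identical shapes.
#' @param n_classes Number of classes.
#' @return `n_classes x n_classes` integer matrix; rows = truth, cols = prediction.
#' @export
confusion_matrix <- function(pred_masks, true_masks, n_classes) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(true_masks)) true_masks <- list(true_masks)
  if (length(pred_masks) == 0L) stop_bad_arg("empty mask list")
  if (length(pred_masks) != length(true_masks)) {
    stop_bad_arg("prediction and truth lists differ in length")
  }
  conf <- matrix(0, n_classes, n_classes)
  for (i in seq_along(pred_masks)) {
    p <- pred_masks[[i]]; t <- true_masks[[i]]
    if (!identical(dim(p), dim(t))) stop_bad_arg("mask pair ", i, " has mismatched shapes")
    if (any(p < 0 | p >= n_classes) || any(t < 0 | t >= n_classes)) {
      stop_bad_arg("labels outside [0, n_classes) in pair ", i)
    }
    # joint code truth*K + pred, tabulated in one pass
    code <- as.integer(t) * n_classes + as.integer(p) + 1L
    conf <- conf + matrix(tabulate(code, nbins = n_classes^2),
                          n_classes, n_classes, byrow = TRUE)
  }
  dimnames(conf) <- list(truth = 0:(n_classes - 1), pred = 0:(n_classes - 1))
  conf
}

#' Segmentation quality metrics: PA, class accuracy, per-class IoU, mIoU
#'
#' Computes pixel accuracy (trace over total), class accuracy (mean per-class
#' recall over classes present in the truth), per-class intersection over
#' union `IoU_c = TP_c / (TP_c + FP_c + FN_c)` and their unweighted mean.
#' Classes absent from both truth and prediction are excluded from the mIoU
#' denominator (avoids 0/0); classes absent from the truth are excluded from
#' class accuracy.
#'
#' @inheritParams confusion_matrix
#' @return A `seg_metrics` list: `pixel_accuracy`, `class_accuracy`,
#'   `per_class_iou` (named, `NA` for classes absent everywhere), `miou`,
#'   and the `confusion` matrix.
#' @export
evaluate_segmentation <- function(pred_masks, true_masks, n_classes) {
  conf <- confusion_matrix(pred_masks, true_masks, n_classes)
  total <- sum(conf)
  if (total == 0) stop_bad_arg("empty masks")
  tp <- diag(conf)
  row_s <- rowSums(conf)   # truth totals
  col_s <- colSums(conf)   # prediction totals

  pa <- sum(tp) / total
  present_truth <- row_s > 0
  acc_class <- mean(tp[present_truth] / row_s[present_truth])

  union <- row_s + col_s - tp
  present_any <- union > 0
  iou <- ifelse(present_any, tp / union, NA_real_)
  names(iou) <- 0:(n_classes - 1)
  miou <- mean(iou[present_any])

  structure(list(pixel_accuracy = pa, class_accuracy = acc_class,
                 per_class_iou = iou, miou = miou, confusion = conf),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> PA=%.4f AccClass=%.4f mIoU=%.4f\n",
              x$pixel_accuracy, x$class_accuracy, x$miou))
  print(round(x$per_class_iou, 4))
  invisible(x)
}
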