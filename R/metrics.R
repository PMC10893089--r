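#' Pixel confusion counts
#'
#' Tallies true/false positives/negatives of a binary prediction against a
#' binary reference.  Counts from many tiles can be accumulated by adding
#' objects with `+`; scores computed from summed counts equal scores
#' computed on the concatenated masks (micro-averaging).
#'
#' @param pred_mask,true_mask Binary arrays of equal shape (no implicit
#'   thresholding: non-binary input is an error).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`, `total`.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (length(pred_mask) != length(true_mask)) {
    stop("pred_mask and true_mask must have equal shape")
  }
  if (!is_binary_array(pred_mask) || !is_binary_array(true_mask)) {
    stop("masks must be strictly binary {0, 1}; threshold before counting")
  }
  p <- pred_mask == 1
  t <- true_mask == 1
  new_confusion(tp = sum(p & t), fp = sum(p & !t),
                tn = sum(!p & !t), fn = sum(!p & t))
}

new_confusion <- function(tp, fp, tn, fn) {
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn),
                 total = as.numeric(tp + fp + tn + fn)),
            class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  new_confusion(e1$tp + e2$tp, e1$fp + e2$fp, e1$tn + e2$tn, e1$fn + e2$fn)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: tp =", x$tp, " fp =", x$fp, " tn =", x$tn,
      " fn =", x$fn, " (", x$total, "pixels )\n")
  invisible(x)
}

#' Segmentation scores from confusion counts
#'
#' The four evaluation statistics, computed on normalised counts
#' (proportions `tp/total` etc.):
#' overall accuracy `OA = (TP + TN) / total`;
#' `F1 = 2 TP / (2 TP + FP + FN)`;
#' foreground intersection-over-union `IoU = TP / (TP + FP + FN)` (the value
#' conventionally reported as "mIoU" in two-class street-tree evaluation);
#' Cohen's kappa `(p0 - pe) / (1 - pe)` with `p0 = OA` and chance agreement
#' `pe = (tp + fp)(tp + fn) + (fp + tn)(fn + tn)` on proportions.  A
#' two-class macro IoU (mean of foreground and background IoU) is reported
#' under its own key to resolve the "mIoU" ambiguity.
#'
#' Degenerate cases are defined rather than NaN: both masks empty
#' (`tp + fp + fn = 0`) gives `f1 = iou = 1`; `pe = 1` gives `kappa = 0`;
#' both are flagged in the `degenerate` field.
#'
#' @param counts A [confusion_counts()].
#' @return List with `oa`, `f1`, `iou`, `macro_iou`, `kappa`, `p0`, `pe`,
#'   and `degenerate` (character vector of triggered flags, possibly empty).
#' @export
seg_scores <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total <= 0) stop("total pixel count must be positive")
  t <- counts$tp / counts$total
  fp <- counts$fp / counts$total
  tn <- counts$tn / counts$total
  fn <- counts$fn / counts$total
  flags <- character(0)
  oa <- t + tn
  if (counts$tp + counts$fp + counts$fn == 0) {
    f1 <- 1; iou <- 1
    flags <- c(flags, "empty_foreground")
  } else {
    f1 <- counts$tp / (counts$tp + (counts$fp + counts$fn) / 2)
    iou <- counts$tp / (counts$tp + counts$fp + counts$fn)
  }
  if (counts$tn + counts$fp + counts$fn == 0) {
    bg_iou <- 1
    flags <- c(flags, "empty_background")
  } else {
    bg_iou <- counts$tn / (counts$tn + counts$fp + counts$fn)
  }
  p0 <- oa
  pe <- (t + fp) * (t + fn) + (fp + tn) * (fn + tn)
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    kappa <- 0
    flags <- c(flags, "chance_agreement_one")
  } else {
    kappa <- (p0 - pe) / (1 - pe)
  }
  list(oa = oa, f1 = f1, iou = iou, macro_iou = (iou + bg_iou) / 2,
       kappa = kappa, p0 = p0, pe = pe, degenerate = flags)
}
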