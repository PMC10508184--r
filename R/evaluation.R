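#' ROC-AUC via the rank (Mann-Whitney) statistic
#'
#' Midranks handle ties, so an uninformative constant score yields exactly
#' 0.5. When the truth contains a single class the AUC is undefined and
#' `NA` is returned, with the reason in the `"reason"` attribute.
#'
#' @param probs numeric scores (higher means more positive).
#' @param truth binary 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` when undefined.
#' @export
roc_auc <- function(probs, truth) {
  assert_binary(truth, "truth")
  if (length(probs) != length(truth)) {
    stop("`probs` and `truth` must be aligned", call. = FALSE)
  }
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) {
    return(structure(NA_real_, reason = "single-class truth"))
  }
  r <- rank(probs)                        # midranks for ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Expected calibration error (equal-width confidence binning)
#'
#' Bins instances by confidence `max(p, 1 - p)` into `bins` equal-width
#' bins over `[0, 1]` and reports the bin-weighted mean absolute gap
#' between within-bin accuracy and within-bin mean confidence:
#' \deqn{\mathrm{ECE} = \sum_b \frac{n_b}{n} \left| \mathrm{acc}_b -
#'   \mathrm{conf}_b \right|.}
#'
#' @param probs predicted positive-class probabilities.
#' @param truth binary 0/1 labels.
#' @param bins number of equal-width bins (default 10).
#' @return ECE in `[0, 1]`.
#' @examples
#' expected_calibration_error(rep(1, 10), rep(c(0, 1), 5))  # 0.5
#' @export
expected_calibration_error <- function(probs, truth, bins = 10L) {
  assert_prob(probs, "probs")
  assert_binary(truth, "truth")
  stopifnot(length(probs) == length(truth), bins >= 1L)
  conf <- pmax(probs, 1 - probs)
  pred <- as.integer(probs >= 0.5)
  correct <- as.numeric(pred == truth)
  idx <- pmin(bins, floor(conf * bins) + 1L)  # conf = 1 falls in the top bin
  n <- length(probs)
  ece <- 0
  for (b in unique(idx)) {
    in_bin <- idx == b
    ece <- ece + sum(in_bin) / n *
      abs(mean(correct[in_bin]) - mean(conf[in_bin]))
  }
  ece
}

#' Classification metrics for binary predictions
#'
#' Computes accuracy, precision, recall, F1, ROC-AUC (rank statistic over
#' `probs`) and expected calibration error, with the confusion-matrix
#' counts. The positive class is 1. Zero-division conventions: with no
#' predicted positives, precision is reported as 0 and the condition is
#' recorded in the `flags` field (likewise recall with no actual
#' positives); F1 is `2PR/(P+R)` when `P + R > 0` and 0 otherwise.
#'
#' @param labels predicted 0/1 labels.
#' @param truth ground-truth 0/1 labels.
#' @param probs optional probabilities for ROC-AUC and ECE; when omitted
#'   those metrics are `NA`.
#' @param bins ECE bin count.
#' @return An object of class `metric_report`: a list with fields
#'   `accuracy`, `precision`, `recall`, `f1`, `roc_auc`, `ece`, `tp`, `fp`,
#'   `tn`, `fn`, `n`, and `flags` (character vector of logged conditions).
#' @examples
#' classification_metrics(c(1, 0, 0, 0), c(1, 1, 0, 0))
#' @export
classification_metrics <- function(labels, truth, probs = NULL, bins = 10L) {
  assert_binary(labels, "labels")
  assert_binary(truth, "truth")
  if (length(labels) != length(truth) ||
      (!is.null(probs) && length(probs) != length(truth))) {
    stop("`labels`, `truth` and `probs` must be aligned", call. = FALSE)
  }
  tp <- sum(labels == 1 & truth == 1)
  fp <- sum(labels == 1 & truth == 0)
  tn <- sum(labels == 0 & truth == 0)
  fn <- sum(labels == 0 & truth == 1)
  n <- length(truth)
  flags <- character()
  if (tp + fp == 0L) {
    precision <- 0
    flags <- c(flags, "no predicted positives: precision reported as 0")
  } else {
    precision <- tp / (tp + fp)
  }
  if (tp + fn == 0L) {
    recall <- 0
    flags <- c(flags, "no actual positives: recall reported as 0")
  } else {
    recall <- tp / (tp + fn)
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  auc <- if (is.null(probs)) NA_real_ else roc_auc(probs, truth)
  if (!is.null(attr(auc, "reason"))) {
    flags <- c(flags, paste("ROC-AUC undefined:", attr(auc, "reason")))
  }
  ece <- if (is.null(probs)) NA_real_ else
    expected_calibration_error(probs, truth, bins)
  structure(list(accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1, roc_auc = as.numeric(auc),
                 ece = ece, tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 flags = flags),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n=%d  acc=%.3f  f1=%.3f  auc=%s  prec=%.3f  rec=%.3f  ece=%s\n",
    x$n, x$accuracy, x$f1,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc)),
    x$precision, x$recall,
    ifelse(is.na(x$ece), "NA", sprintf("%.3f", x$ece))))
  for (fl in x$flags) cat("  note:", fl, "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, f1 = x$f1, roc_auc = x$roc_auc, ece = x$ece,
             tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, n = x$n)
}
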