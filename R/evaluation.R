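# Pixel-level evaluation: confusion counts, accuracy/recall/precision/F1,
# confluency (predicted foreground area fraction) and confluency error
# against a staining-based standard.

#' Pixelwise confusion counts between a predicted and a reference mask
#'
#' @param pred,truth 0/1 integer matrices of identical dimensions.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn` and `n` (total pixels).
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_mask(pred)
  truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` dimensions differ", call. = FALSE)
  }
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = length(pred)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d (N = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and
#' F1 `2PR/(P+R)`. A ratio with a zero denominator is undefined and
#' reported as `NA` (distinct from 0); aggregation functions exclude `NA`
#' values and report how many were excluded.
#'
#' @param counts A [confusion_counts] object.
#' @return An object of class `segmentation_metrics` with fields
#'   `accuracy`, `recall`, `precision`, `f1`.
#' @export
compute_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    stop("`counts` must be a confusion_counts object", call. = FALSE)
  }
  with(counts, {
    if (n == 0L) stop("total pixel count is zero", call. = FALSE)
    accuracy <- (tp + tn) / n
    recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    f1 <- if (is.na(recall) || is.na(precision) || precision + recall == 0) {
      NA_real_  # 0/0: undefined, excluded from aggregates
    } else {
      2 * precision * recall / (precision + recall)
    }
    structure(list(accuracy = accuracy, recall = recall,
                   precision = precision, f1 = f1),
              class = "segmentation_metrics")
  })
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf(
    "<segmentation_metrics> accuracy %.4f  recall %s  precision %s  f1 %s\n",
    x$accuracy, .fmt_na(x$recall), .fmt_na(x$precision), .fmt_na(x$f1)))
  invisible(x)
}

.fmt_na <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)

#' Confluency of a segmentation mask
#'
#' Confluency is the fraction of the image area covered by (predicted)
#' cells: foreground pixel count over total pixel count, equivalently
#' `(TP + FP) / N` for any reference pairing.
#'
#' @param mask 0/1 integer matrix.
#' @return Fraction in `[0, 1]`.
#' @export
compute_confluency <- function(mask) {
  mask <- as_mask(mask)
  if (length(mask) == 0L) stop("empty mask", call. = FALSE)
  mean(mask == 1L)
}

#' Confluency error against a standard
#'
#' The standard confluency is the stained-cell area fraction of the same
#' field of view (produced externally, e.g. by a CellProfiler pipeline on
#' the stained image). The headline error is the absolute difference; the
#' signed difference is available via `signed = TRUE`.
#'
#' @param method Confluency estimated by the segmentation method, in `[0, 1]`.
#' @param standard Standard (stained-reference) confluency, in `[0, 1]`.
#' @param signed If `TRUE` return `method - standard` instead of its
#'   absolute value.
#' @return Dimensionless error.
#' @export
confluency_error <- function(method, standard, signed = FALSE) {
  if (!is.numeric(method) || method < 0 || method > 1 ||
      !is.numeric(standard) || standard < 0 || standard > 1) {
    stop("confluency values must lie in [0, 1]", call. = FALSE)
  }
  d <- method - standard
  if (signed) d else abs(d)
}

#' Evaluate a batch of predicted masks against ground truth
#'
#' Computes per-image confusion counts, metrics and confluency, plus two
#' aggregates: the unweighted mean of the per-image metrics (undefined
#' values excluded, with the exclusion count reported) and pooled-pixel
#' metrics computed from the summed confusion counts.
#'
#' @param pred_masks,truth_masks Lists of 0/1 matrices of equal length.
#' @param standards Optional numeric vector of standard confluencies (one
#'   per image) for confluency-error reporting.
#' @param ids Optional character vector of image identifiers.
#' @return A list of class `batch_evaluation`: `per_image` (data frame with
#'   one row per image), `means` (named list of mean metrics and the count
#'   of undefined values excluded), and `pooled` (metrics over summed
#'   counts).
#' @export
evaluate_batch <- function(pred_masks, truth_masks, standards = NULL,
                           ids = NULL) {
  n <- length(pred_masks)
  if (n != length(truth_masks)) {
    stop("`pred_masks` and `truth_masks` lengths differ", call. = FALSE)
  }
  if (!is.null(standards) && length(standards) != n) {
    stop("`standards` length differs from the mask lists", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_len(n))
  rows <- vector("list", n)
  tot <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_len(n)) {
    cc <- confusion_counts(pred_masks[[i]], truth_masks[[i]])
    m <- compute_metrics(cc)
    conf <- compute_confluency(pred_masks[[i]])
    std <- if (is.null(standards)) NA_real_ else standards[i]
    err <- if (is.na(std)) NA_real_ else confluency_error(conf, std)
    tot <- tot + c(cc$tp, cc$fp, cc$fn, cc$tn)
    rows[[i]] <- data.frame(
      image_id = ids[i], tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
      accuracy = m$accuracy, recall = m$recall, precision = m$precision,
      f1 = m$f1, confluency = conf, standard_confluency = std, error = err,
      stringsAsFactors = FALSE)
  }
  per_image <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "recall", "precision", "f1", "confluency",
                   "error")
  means <- lapply(metric_cols, function(cl) mean(per_image[[cl]], na.rm = TRUE))
  names(means) <- metric_cols
  means$n_undefined <- sum(is.na(per_image[, c("recall", "precision", "f1")]))
  pooled_counts <- structure(
    list(tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]],
         tn = tot[["tn"]], n = sum(tot)),
    class = "confusion_counts")
  structure(list(per_image = per_image, means = means,
                 pooled = compute_metrics(pooled_counts)),
            class = "batch_evaluation")
}

#' @export
print.batch_evaluation <- function(x, ...) {
  cat(sprintf("<batch_evaluation> %d images\n", nrow(x$per_image)))
  cat(sprintf("  mean: accuracy %.4f  recall %.4f  precision %.4f  f1 %.4f\n",
              x$means$accuracy, x$means$recall, x$means$precision,
              x$means$f1))
  if (!all(is.na(x$per_image$error))) {
    cat(sprintf("  mean confluency error: %.4f\n", x$means$error))
  }
  invisible(x)
}
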